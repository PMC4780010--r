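#' Robust within-family kinship coefficient
#'
#' Moment-based kinship estimator for a pair of genotype vectors from the
#' same population (Manichaikul et al. 2010, the within-family KING-robust
#' form):
#' \deqn{\hat\phi = \frac{N_{Aa,Aa} - 2\,N_{AA,aa}}{N_{Aa,i} + N_{Aa,j}}}
#' where \eqn{N_{Aa,Aa}} counts sites at which both samples are
#' heterozygous, \eqn{N_{AA,aa}} counts opposite homozygotes, and
#' \eqn{N_{Aa,i}} is the heterozygote count of sample i. Sites with a
#' missing genotype in either sample are dropped pairwise. Expected values:
#' 0.5 for duplicates/monozygotic twins, about 0.25 for parent-offspring,
#' about 0 for unrelated pairs.
#'
#' @param genotypes_i,genotypes_j Equal-length character vectors of
#'   genotype codes (see [genotype_codes()]).
#' @param id_i,id_j Sample identifiers used in reports and error messages.
#'
#' @return An object of class `kinship_estimate`: list with the four counts,
#'   the number of sites compared, and `phi`.
#' @references Manichaikul A et al. (2010) Robust relationship inference in
#'   genome-wide association studies. Bioinformatics 26(22):2867-2873.
#' @examples
#' g <- c("het", "hom_ref", "het", "hom_alt")
#' kinship(g, g)$phi  # identical vectors give 0.5
#' @export
kinship <- function(genotypes_i, genotypes_j, id_i = "i", id_j = "j") {
  if (length(genotypes_i) != length(genotypes_j) || length(genotypes_i) < 1L) {
    stop("genotype vectors must have equal, positive length", call. = FALSE)
  }
  keep <- genotypes_i != "missing" & genotypes_j != "missing"
  gi <- genotypes_i[keep]
  gj <- genotypes_j[keep]
  n_het_i <- sum(gi == "het")
  n_het_j <- sum(gj == "het")
  n_both_het <- sum(gi == "het" & gj == "het")
  n_opposite_hom <- sum((gi == "hom_ref" & gj == "hom_alt") |
                          (gi == "hom_alt" & gj == "hom_ref"))
  denom <- n_het_i + n_het_j
  if (denom == 0L) {
    stop(sprintf("kinship undefined for pair (%s, %s): no heterozygous sites",
                 id_i, id_j), call. = FALSE)
  }
  structure(list(sample_i = id_i, sample_j = id_j,
                 n_both_het = n_both_het, n_opposite_hom = n_opposite_hom,
                 n_het_i = n_het_i, n_het_j = n_het_j,
                 n_sites = sum(keep),
                 phi = (n_both_het - 2 * n_opposite_hom) / denom),
            class = "kinship_estimate")
}

#' @export
print.kinship_estimate <- function(x, ...) {
  cat(sprintf("kinship(%s, %s): phi = %.4f over %d sites\n",
              x$sample_i, x$sample_j, x$phi, x$n_sites))
  invisible(x)
}

#' Kinship-based trio quality control
#'
#' Computes father-child and mother-child kinship for every family and
#' flags trios for exclusion. A trio is excluded when at least one
#' parent-child kinship falls below `exclusion_threshold`; with
#' `strict_boundary = TRUE` a kinship exactly at the threshold also fails,
#' so cohorts excluding boundary trios (kinship exactly 0.17) are
#' reproducible. The expected parent-child range in exome data is roughly
#' 0.17 to 0.35.
#'
#' @param cohort A `trio_cohort` (from [generate_trio_cohort()] or
#'   [read_trio_vcf()]) or its `variants` data frame with the trio genotype
#'   columns.
#' @param exclusion_threshold Kinship below which a parent-child pair fails
#'   (default 0.17).
#' @param strict_boundary If `TRUE`, a kinship exactly equal to the
#'   threshold also fails.
#'
#' @return Data frame with one row per family: `family`, `phi_father_child`,
#'   `phi_mother_child`, `excluded`, `reason`.
#' @export
qc_trios <- function(cohort, exclusion_threshold = 0.17,
                     strict_boundary = FALSE) {
  v <- if (inherits(cohort, "trio_cohort")) cohort$variants else cohort
  assert_columns(v, c("family", "pos", "gt_child", "gt_father", "gt_mother"),
                 "cohort variants")
  fams <- unique(v$family)
  rows <- lapply(fams, function(fam) {
    gc <- member_genotypes(v, fam, "child")
    gf <- member_genotypes(v, fam, "father")
    gm <- member_genotypes(v, fam, "mother")
    phi_fc <- kinship(gf, gc, paste0(fam, "-father"), paste0(fam, "-child"))$phi
    phi_mc <- kinship(gm, gc, paste0(fam, "-mother"), paste0(fam, "-child"))$phi
    fails <- if (strict_boundary) {
      c(phi_fc, phi_mc) <= exclusion_threshold
    } else {
      c(phi_fc, phi_mc) < exclusion_threshold
    }
    reason <- if (!any(fails)) {
      ""
    } else {
      rel <- if (strict_boundary) "<=" else "<"
      paste0(c("father-child", "mother-child")[fails], " kinship ", rel, " ",
             format(exclusion_threshold), collapse = "; ")
    }
    data.frame(family = fam, phi_father_child = phi_fc,
               phi_mother_child = phi_mc, excluded = any(fails),
               reason = reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
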