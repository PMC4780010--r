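#' Simulate a trio cohort with known ground truth
#'
#' Generates per-family annotated trio variant tables. Parental genotypes
#' are drawn under Hardy-Weinberg equilibrium at per-site allele
#' frequencies uniform on `maf_range`; the child inherits one allele
#' sampled from each parent, so every non-planted site is Mendelian
#' consistent. Planted events override the Mendelian draw:
#'
#' * true de novo sites: parents homozygous reference, child heterozygous,
#'   consequence missense, nonsense or splice site;
#' * recessive sites: both parents heterozygous, child homozygous
#'   alternate, missense, MAF in the rare band (0.01-0.05);
#' * very-rare high-impact sites: one parent heterozygous (the other
#'   homozygous reference), child heterozygous, nonsense or splice site,
#'   MAF below 0.01 or absent (novel);
#' * decoys: de novo genotype pattern, but each violates exactly one
#'   triage criterion (a parent depth of 9, synonymous consequence, or a
#'   gene outside the brain-expressed set, cycling in that order).
#'
#' Background sites draw their consequence from synonymous/other/missense
#' and their frequency from `maf_range` (common under the default range),
#' so with default settings only planted sites can satisfy the triage
#' rules and truth-label recovery is exact.
#'
#' @param config A [sim_config()] object.
#'
#' @return An object of class `trio_cohort`: a list with
#'   `variants` (one row per family x site, trio genotypes and depths plus
#'   gene, consequence, maf_max and cytogenetic band annotations),
#'   `truth` (per planted site: family, position, event flags, decoy type),
#'   `brain_genes` (character vector: every simulated gene except the
#'   planted non-brain decoy genes), `families`, and `config`.
#' @examples
#' cfg <- sim_config(n_trios = 2, n_sites = 200,
#'                   n_true_denovo_per_trio = 2, rng_seed = 7)
#' cohort <- generate_trio_cohort(cfg)
#' table(cohort$truth$event)
#' @export
generate_trio_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)

  families <- sprintf("F%02d", seq_len(config$n_trios))
  n <- config$n_sites
  per_family <- lapply(families, function(fam) {
    pos <- 10000L * seq_len(n)
    block <- (seq_len(n) - 1L) %/% 10L
    gene <- sprintf("%s_G%04d", fam, block + 1L)
    band <- sprintf("1q%d.%d", block %% 40L + 1L, block %% 3L + 1L)
    maf <- runif(n, config$maf_range[1], config$maf_range[2])
    consequence <- sample(c("synonymous", "other", "missense"), n,
                          replace = TRUE, prob = c(0.4, 0.4, 0.2))
    gt_f <- hwe_genotypes(maf)
    gt_m <- hwe_genotypes(maf)
    gt_c <- dosage_gt(transmit_allele(gt_f) + transmit_allele(gt_m))
    dp <- matrix(sim_depth(3L * n, config$depth_mean), ncol = 3L)

    k_dn <- config$n_true_denovo_per_trio
    k_rc <- config$n_recessive_per_trio
    k_vr <- config$n_vrare_high_per_trio
    k_dc <- config$n_decoy_per_trio
    planted <- sample.int(n, k_dn + k_rc + k_vr + k_dc)
    idx_dn <- planted[seq_len(k_dn)]
    idx_rc <- planted[k_dn + seq_len(k_rc)]
    idx_vr <- planted[k_dn + k_rc + seq_len(k_vr)]
    idx_dc <- planted[k_dn + k_rc + k_vr + seq_len(k_dc)]

    if (k_dn > 0L) {
      gt_f[idx_dn] <- "hom_ref"; gt_m[idx_dn] <- "hom_ref"
      gt_c[idx_dn] <- "het"
      consequence[idx_dn] <- sample(c("missense", "nonsense", "splice_site"),
                                    k_dn, replace = TRUE)
    }
    if (k_rc > 0L) {
      gt_f[idx_rc] <- "het"; gt_m[idx_rc] <- "het"
      gt_c[idx_rc] <- "hom_alt"
      consequence[idx_rc] <- "missense"
      maf[idx_rc] <- runif(k_rc, 0.015, 0.045)
    }
    if (k_vr > 0L) {
      from_father <- rbinom(k_vr, 1L, 0.5) == 1L
      gt_f[idx_vr] <- ifelse(from_father, "het", "hom_ref")
      gt_m[idx_vr] <- ifelse(from_father, "hom_ref", "het")
      gt_c[idx_vr] <- "het"
      consequence[idx_vr] <- sample(c("nonsense", "splice_site"),
                                    k_vr, replace = TRUE)
      novel <- rbinom(k_vr, 1L, 0.5) == 1L
      maf[idx_vr] <- ifelse(novel, NA_real_, runif(k_vr, 5e-4, 0.009))
    }
    decoy_type <- character(0)
    if (k_dc > 0L) {
      gt_f[idx_dc] <- "hom_ref"; gt_m[idx_dc] <- "hom_ref"
      gt_c[idx_dc] <- "het"
      consequence[idx_dc] <- "missense"
      decoy_type <- rep(c("low_depth", "synonymous", "non_brain"),
                        length.out = k_dc)
      dp[idx_dc[decoy_type == "low_depth"], 2L] <- 9L
      consequence[idx_dc[decoy_type == "synonymous"]] <- "synonymous"
      nb <- idx_dc[decoy_type == "non_brain"]
      gene[nb] <- sprintf("%s_NB%03d", fam, seq_along(nb))
    }

    variants <- data.frame(
      family = fam, chrom = "1", pos = pos, rsid = ".",
      ref = "A", alt = "G",
      gene = gene, consequence = consequence, maf_max = maf, band = band,
      gt_child = gt_c, gt_father = gt_f, gt_mother = gt_m,
      dp_child = dp[, 1L], dp_father = dp[, 2L], dp_mother = dp[, 3L],
      stringsAsFactors = FALSE
    )
    truth_idx <- c(idx_dn, idx_rc, idx_vr, idx_dc)
    truth <- data.frame(
      family = rep(fam, length(truth_idx)),
      chrom = rep("1", length(truth_idx)),
      pos = pos[truth_idx],
      gene = gene[truth_idx],
      event = c(rep("de_novo", k_dn), rep("recessive", k_rc),
                rep("vrare_high", k_vr), rep("decoy", k_dc)),
      decoy_type = c(rep(NA_character_, k_dn + k_rc + k_vr), decoy_type),
      stringsAsFactors = FALSE
    )
    list(variants = variants, truth = truth)
  })

  variants <- do.call(rbind, lapply(per_family, `[[`, "variants"))
  truth <- do.call(rbind, lapply(per_family, `[[`, "truth"))
  rownames(variants) <- NULL
  rownames(truth) <- NULL
  brain_genes <- sort(unique(variants$gene[!grepl("_NB", variants$gene)]))

  structure(list(variants = variants, truth = truth,
                 brain_genes = brain_genes, families = families,
                 config = config),
            class = "trio_cohort")
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat("trio_cohort:", length(x$families), "families,",
      nrow(x$variants), "variant records,",
      nrow(x$truth), "planted events\n")
  invisible(x)
}

#' Extract one family member's genotype vector from a cohort
#'
#' @param cohort A `trio_cohort` or its `variants` data frame.
#' @param family Family identifier.
#' @param member One of `"child"`, `"father"`, `"mother"`.
#' @return Character vector of genotype codes, ordered by position.
#' @export
member_genotypes <- function(cohort, family, member = c("child", "father", "mother")) {
  member <- match.arg(member)
  v <- if (inherits(cohort, "trio_cohort")) cohort$variants else cohort
  assert_columns(v, c("family", "pos", paste0("gt_", member)), "cohort variants")
  v <- v[v$family == family, , drop = FALSE]
  if (nrow(v) == 0L) stop("no records for family ", family, call. = FALSE)
  v[[paste0("gt_", member)]][order(v$pos)]
}
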