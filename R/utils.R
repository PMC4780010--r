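#' Genotype codes used throughout the package
#'
#' Biallelic genotypes are encoded as one of `"hom_ref"`, `"het"`,
#' `"hom_alt"` or `"missing"`. Multi-allelic sites are not modelled.
#'
#' @return Character vector of the four recognized genotype codes.
#' @export
genotype_codes <- function() c("hom_ref", "het", "hom_alt", "missing")

#' Consequence classes recognized by the triage rules
#'
#' @return Character vector of recognized variant consequence classes.
#' @export
consequence_codes <- function() {
  c("missense", "nonsense", "splice_site", "synonymous", "other")
}

# Stop with a clear message if required columns are absent.
assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Alt-allele dosage (0/1/2, NA for missing) from genotype codes.
gt_dosage <- function(gt) {
  unname(c(hom_ref = 0, het = 1, hom_alt = 2,
           missing = NA_real_)[gt])
}

# Genotype code from alt-allele dosage.
dosage_gt <- function(d) {
  c("hom_ref", "het", "hom_alt")[d + 1L]
}

# Draw one genotype per site under Hardy-Weinberg at alt frequency p.
hwe_genotypes <- function(p) {
  u <- runif(length(p))
  q <- 1 - p
  dosage_gt(as.integer(u > q^2) + as.integer(u > q^2 + 2 * p * q))
}

# One transmitted allele (0 or 1) per genotype; hets transmit at random.
transmit_allele <- function(gt) {
  a <- integer(length(gt))
  a[gt == "hom_alt"] <- 1L
  het <- gt == "het"
  a[het] <- rbinom(sum(het), 1L, 0.5)
  a
}

# Read depths ~ Poisson(mean) truncated below at 1.
sim_depth <- function(n, depth_mean) {
  pmax(1L, rpois(n, depth_mean))
}
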