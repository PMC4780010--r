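#' Configuration for the synthetic trio cohort generator
#'
#' Bundles and validates every tunable of the simulators in one object.
#' Identical configurations (including `rng_seed`) produce bit-identical
#' output from every generator.
#'
#' @param n_trios Number of families to simulate.
#' @param n_sites Number of biallelic sites per family.
#' @param maf_range Length-2 numeric, range of simulated alternate allele
#'   frequencies; both endpoints in (0, 0.5].
#' @param n_true_denovo_per_trio Number of true de novo moderate/high-impact
#'   heterozygous sites planted per trio (parents homozygous reference).
#' @param n_recessive_per_trio Number of rare recessive configurations
#'   planted per trio (both parents heterozygous, child homozygous
#'   alternate, missense, MAF in the rare band).
#' @param n_vrare_high_per_trio Number of very-rare/novel high-impact
#'   heterozygous sites planted per trio (inherited from exactly one
#'   parent).
#' @param n_decoy_per_trio Number of decoy sites per trio; each decoy looks
#'   like a de novo candidate but violates exactly one triage criterion
#'   (read depth 9, synonymous consequence, or a gene absent from the
#'   brain-expressed set, cycling in that order).
#' @param depth_mean Mean of the per-site read-depth distribution
#'   (Poisson truncated at 1).
#' @param cnv_spec List of CNV event descriptions built with [cnv_event()];
#'   consumed by [generate_cnv_calls()].
#' @param ppi_spec List describing the interactome generator: `n_nodes`,
#'   `power` (preferential-attachment exponent), `edges_per_step`,
#'   `evidence_fn` (function mapping an edge count to integer evidence
#'   counts >= 1; default 1 + Poisson(1.5)), `seed_genes` (symbols planted
#'   as nodes).
#' @param rng_seed Integer seed; the generators are deterministic given the
#'   full configuration.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_trio_cohort()], [generate_cnv_calls()],
#'   [generate_ppi()]
#' @export
sim_config <- function(n_trios = 4L,
                       n_sites = 2000L,
                       maf_range = c(0.05, 0.5),
                       n_true_denovo_per_trio = 0L,
                       n_recessive_per_trio = 0L,
                       n_vrare_high_per_trio = 0L,
                       n_decoy_per_trio = 0L,
                       depth_mean = 40,
                       cnv_spec = list(),
                       ppi_spec = list(),
                       rng_seed = 1L) {
  counts <- c(n_trios = n_trios, n_sites = n_sites,
              n_true_denovo_per_trio = n_true_denovo_per_trio,
              n_recessive_per_trio = n_recessive_per_trio,
              n_vrare_high_per_trio = n_vrare_high_per_trio,
              n_decoy_per_trio = n_decoy_per_trio)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("all counts must be non-negative integers", call. = FALSE)
  }
  if (n_trios < 1L) stop("n_trios must be at least 1", call. = FALSE)
  if (!is.numeric(maf_range) || length(maf_range) != 2L ||
      maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5] with lower <= upper",
         call. = FALSE)
  }
  if (!is.numeric(depth_mean) || depth_mean <= 0) {
    stop("depth_mean must be positive", call. = FALSE)
  }
  planted <- n_true_denovo_per_trio + n_recessive_per_trio +
    n_vrare_high_per_trio + n_decoy_per_trio
  if (planted > n_sites) {
    stop(sprintf(
      "contradictory configuration: %d planted sites requested but only %d sites per trio",
      planted, n_sites), call. = FALSE)
  }
  ppi_defaults <- list(n_nodes = 200L, power = 1, edges_per_step = 2L,
                       evidence_fn = NULL, seed_genes = character())
  ppi_spec <- utils::modifyList(ppi_defaults, ppi_spec)
  if (ppi_spec$n_nodes < 2L) {
    stop("ppi_spec$n_nodes must be at least 2", call. = FALSE)
  }
  structure(list(
    n_trios = as.integer(n_trios),
    n_sites = as.integer(n_sites),
    maf_range = as.numeric(maf_range),
    n_true_denovo_per_trio = as.integer(n_true_denovo_per_trio),
    n_recessive_per_trio = as.integer(n_recessive_per_trio),
    n_vrare_high_per_trio = as.integer(n_vrare_high_per_trio),
    n_decoy_per_trio = as.integer(n_decoy_per_trio),
    depth_mean = depth_mean,
    cnv_spec = cnv_spec,
    ppi_spec = ppi_spec,
    rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_trios, "trios x", x$n_sites, "sites;",
      "planted per trio:", x$n_true_denovo_per_trio, "de novo,",
      x$n_recessive_per_trio, "recessive,",
      x$n_vrare_high_per_trio, "very-rare high,",
      x$n_decoy_per_trio, "decoys;",
      length(x$cnv_spec), "CNV events; seed", x$rng_seed, "\n")
  invisible(x)
}
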