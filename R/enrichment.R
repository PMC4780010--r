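#' Upper-tail hypergeometric probability
#'
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` annotated genes when `n` genes are drawn without
#' replacement from a universe of `N` genes of which `K` are annotated.
#' Computed through the cumulative distribution in [stats::phyper()],
#' which works on log scale internally and is stable for extreme tails.
#'
#' @param k Observed overlap count.
#' @param K Category (annotation) size within the universe.
#' @param n Study-set size.
#' @param N Universe size.
#' @return Probability in (0, 1\].
#' @examples
#' hypergeom_upper(5, 5, 5, 20)  # 1 / choose(20, 5)
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n)) {
    stop(sprintf(
      "impossible hypergeometric configuration: k=%s K=%s n=%s N=%s",
      k, K, n, N), call. = FALSE)
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up adjustment (with monotonicity enforcement,
#' capped at 1) or Bonferroni (`min(1, m p)`), delegating to
#' [stats::p.adjust()].
#'
#' @param pvals Numeric vector of raw p-values in (0, 1\].
#' @param method `"BH"` or `"bonferroni"`.
#' @return Numeric vector of adjusted p-values.
#' @export
adjust_pvalues <- function(pvals, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (length(pvals) == 0L) return(numeric(0))
  if (any(pvals <= 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = method)
}

#' Hypergeometric over-representation analysis
#'
#' Tests every category for over-representation of the study gene set
#' against a reference universe, adjusts across categories, and applies
#' the reporting rule: significant terms are those with adjusted p-value
#' below `alpha`, and at most the `top_k` best are reported. Study genes
#' outside the universe are clipped with a warning. Results are ordered
#' by adjusted p-value, then raw p-value, then term identifier, so the
#' output does not depend on category iteration order.
#'
#' @param study Character vector of study gene symbols.
#' @param categories Named list mapping term identifiers to character
#'   vectors of member genes.
#' @param universe Character vector: the reference gene universe.
#' @param method Adjustment method, `"BH"` (default) or `"bonferroni"`.
#' @param alpha Significance level on the adjusted p-value (default
#'   0.05).
#' @param top_k Maximum number of reported terms (default 10).
#' @return Data frame with one row per term: `term`, `k` (overlap), `K`
#'   (category size in universe), `n` (study size), `N` (universe size),
#'   `p`, `p_adj`, `genes` (comma-separated overlap), and `reported`.
#' @export
ora <- function(study, categories, universe, method = c("BH", "bonferroni"),
                alpha = 0.05, top_k = 10L) {
  method <- match.arg(method)
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  study <- unique(study)
  outside <- setdiff(study, universe)
  if (length(outside) > 0L) {
    warning(length(outside), " study gene(s) outside the universe; clipped")
    study <- intersect(study, universe)
  }
  if (is.null(names(categories)) || any(names(categories) == "")) {
    stop("categories must be a named list", call. = FALSE)
  }
  terms <- sort(names(categories))
  n <- length(study)
  N <- length(universe)
  rows <- lapply(terms, function(tm) {
    members <- intersect(unique(categories[[tm]]), universe)
    hit <- intersect(members, study)
    data.frame(term = tm, k = length(hit), K = length(members), n = n,
               N = N,
               p = hypergeom_upper(length(hit), length(members), n, N),
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_pvalues(out$p, method)
  out <- out[order(out$p_adj, out$p, out$term), , drop = FALSE]
  n_sig <- sum(out$p_adj < alpha)
  out$reported <- seq_len(nrow(out)) <= min(top_k, n_sig)
  rownames(out) <- NULL
  out[, c("term", "k", "K", "n", "N", "p", "p_adj", "genes", "reported")]
}
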