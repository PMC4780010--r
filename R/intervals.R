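#' Test whether two genomic intervals overlap
#'
#' Intervals are 1-based and closed on both ends. Two intervals overlap
#' when they share a chromosome and at least one base; with
#' `min_fraction > 0` the intersection must additionally cover at least
#' that fraction of interval `a`. `min_fraction = 0` reduces to
#' any-overlap.
#'
#' @param a,b Lists or single-row data frames with `chrom`, `start`,
#'   `end`.
#' @param min_fraction Required intersection / length(a) fraction in
#'   \[0, 1\].
#' @return Logical flag.
#' @examples
#' overlaps(list(chrom = "1", start = 100, end = 200),
#'          list(chrom = "1", start = 200, end = 300))  # TRUE, 1 bp
#' @export
overlaps <- function(a, b, min_fraction = 0) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  if (a$start > a$end || b$start > b$end) {
    stop("interval start must not exceed end", call. = FALSE)
  }
  if (as.character(a$chrom) != as.character(b$chrom)) return(FALSE)
  inter <- min(a$end, b$end) - max(a$start, b$start) + 1
  if (inter < 1) return(FALSE)
  inter / (a$end - a$start + 1) >= min_fraction
}

# All query/subject index pairs whose intervals overlap (same chromosome,
# >= 1 shared base, intersection covering >= min_fraction of the query).
# Interval columns are 1-based closed. Built on GenomicRanges.
overlap_hits <- function(query, subject, min_fraction = 0) {
  if (nrow(query) == 0L || nrow(subject) == 0L) {
    return(data.frame(query_idx = integer(), subject_idx = integer()))
  }
  gq <- GenomicRanges::GRanges(as.character(query$chrom),
                               IRanges::IRanges(query$start, query$end))
  gs <- GenomicRanges::GRanges(as.character(subject$chrom),
                               IRanges::IRanges(subject$start, subject$end))
  # disjoint chromosome sets are an ordinary no-overlap case, not a warning
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gq, gs))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (min_fraction > 0 && length(qi) > 0L) {
    inter <- pmin(query$end[qi], subject$end[si]) -
      pmax(query$start[qi], subject$start[si]) + 1
    frac <- inter / (query$end[qi] - query$start[qi] + 1)
    keep <- frac >= min_fraction
    qi <- qi[keep]
    si <- si[keep]
  }
  data.frame(query_idx = qi, subject_idx = si)
}
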