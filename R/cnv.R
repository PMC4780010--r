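#' Quality filter for exome CNV calls
#'
#' Retains calls with at least `min_exons` targeted exons, length of at
#' least `min_length` base pairs, and both phred-scaled qualities (some
#' CNV event in the interval; region not diploid) of at least
#' `min_quality`. All bounds are inclusive.
#'
#' @param calls Data frame of CNV calls with columns `sample`, `chrom`,
#'   `start`, `end` (1-based closed), `type` (`"DEL"`/`"DUP"`),
#'   `n_exons`, `q_some`, `q_nondiploid`.
#' @param min_exons,min_length,min_quality Inclusive thresholds
#'   (defaults 3 exons, 1000 bp, phred 90).
#' @return The retained calls; dropped calls are recorded in the
#'   `"dropped"` attribute with the first failing criterion.
#' @export
quality_filter <- function(calls, min_exons = 3L, min_length = 1000L,
                           min_quality = 90) {
  assert_columns(calls, c("sample", "chrom", "start", "end", "type",
                          "n_exons", "q_some", "q_nondiploid"), "calls")
  len <- calls$end - calls$start + 1
  fail <- rep(NA_character_, nrow(calls))
  fail[is.na(fail) & calls$n_exons < min_exons] <- "n_exons"
  fail[is.na(fail) & len < min_length] <- "length"
  fail[is.na(fail) & calls$q_some < min_quality] <- "q_some"
  fail[is.na(fail) & calls$q_nondiploid < min_quality] <- "q_nondiploid"
  kept <- calls[is.na(fail), , drop = FALSE]
  rownames(kept) <- NULL
  dropped <- calls[!is.na(fail), , drop = FALSE]
  dropped$failed <- fail[!is.na(fail)]
  attr(kept, "dropped") <- dropped
  kept
}

#' Remove CNV calls overlapping population controls
#'
#' A call is removed when it overlaps any control interval, of either CNV
#' type, by at least one base (or by `min_fraction` of the call when
#' configured).
#'
#' @param calls CNV call data frame (see [quality_filter()]).
#' @param control_cnvs Data frame of control intervals with columns
#'   `chrom`, `start`, `end` (1-based closed; `type` optional and
#'   ignored).
#' @param min_fraction Required overlap as a fraction of the call
#'   (default 0 = any overlap).
#' @return The retained calls.
#' @export
remove_control_overlaps <- function(calls, control_cnvs, min_fraction = 0) {
  if (is.null(control_cnvs) || nrow(control_cnvs) == 0L) {
    warning("empty control CNV set: no calls removed")
    return(calls)
  }
  assert_columns(control_cnvs, c("chrom", "start", "end"), "control_cnvs")
  hits <- overlap_hits(calls, control_cnvs, min_fraction)
  kept <- calls[!seq_len(nrow(calls)) %in% hits$query_idx, , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

#' Remove CNV calls recurrent in healthy parents
#'
#' A call is removed when more than `max_parents` distinct parent samples
#' carry an overlapping call of the same CNV type (strictly greater:
#' exactly `max_parents` carriers are retained).
#'
#' @param calls Child CNV call data frame.
#' @param parent_cohort_calls Parent CNV call data frame (`sample`,
#'   `chrom`, `start`, `end`, `type`).
#' @param max_parents Maximum tolerated number of carrier parents
#'   (default 3).
#' @param min_fraction Overlap fraction passed to the interval match.
#' @return The retained calls, with a `n_carrier_parents` column added.
#' @export
parent_frequency_filter <- function(calls, parent_cohort_calls,
                                    max_parents = 3L, min_fraction = 0) {
  if (is.null(parent_cohort_calls) || nrow(parent_cohort_calls) == 0L) {
    calls$n_carrier_parents <- 0L
    return(calls)
  }
  assert_columns(parent_cohort_calls,
                 c("sample", "chrom", "start", "end", "type"),
                 "parent_cohort_calls")
  n_carriers <- count_carrier_parents(calls, parent_cohort_calls, min_fraction)
  calls$n_carrier_parents <- n_carriers
  kept <- calls[n_carriers <= max_parents, , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

# Distinct parent samples carrying an overlapping same-type call, per call.
count_carrier_parents <- function(calls, parent_cohort_calls, min_fraction = 0) {
  if (nrow(calls) == 0L) return(integer(0))
  if (is.null(parent_cohort_calls) || nrow(parent_cohort_calls) == 0L) {
    return(rep(0L, nrow(calls)))
  }
  hits <- overlap_hits(calls, parent_cohort_calls, min_fraction)
  same_type <- calls$type[hits$query_idx] ==
    parent_cohort_calls$type[hits$subject_idx]
  hits <- hits[same_type, , drop = FALSE]
  n <- rep(0L, nrow(calls))
  if (nrow(hits) > 0L) {
    cnt <- tapply(parent_cohort_calls$sample[hits$subject_idx],
                  hits$query_idx, function(s) length(unique(s)))
    n[as.integer(names(cnt))] <- as.integer(cnt)
  }
  n
}

#' Heterozygous-SNV rate inside a deletion call
#'
#' Fraction of SNV sites inside the call interval (same sample) with a
#' heterozygous genotype call. A true hemizygous deletion should show no
#' heterozygous sites; a rate above 10% marks the deletion as a likely
#' false positive.
#'
#' @param call Single CNV call (one-row data frame or list with `sample`,
#'   `chrom`, `start`, `end`).
#' @param sites Site allele evidence data frame with columns `sample`,
#'   `chrom`, `pos`, `gt`, `alt_reads`, `total_reads`.
#' @return Fraction in \[0, 1\], or `NA` when no site falls inside the
#'   interval (the caller retains such calls with a no-evidence flag).
#' @export
het_rate <- function(call, sites) {
  s <- sites_in_call(call, sites)
  if (nrow(s) == 0L) return(NA_real_)
  mean(s$gt == "het")
}

#' Mean B-allele frequency inside a duplication call
#'
#' Mean of `alt_reads / total_reads` over heterozygous-called sites with
#' at least one read inside the call interval. In a true duplication het
#' sites sit near 1/3 or 2/3; a mean in the open interval (0.4, 0.6)
#' marks the duplication as a likely false positive. With
#' `folded = TRUE` the mean of the folded deviation `|BAF - 0.5|` is
#' returned instead, which separates balanced mixtures of 1/3 and 2/3
#' sites from genuinely diploid signal.
#'
#' @inheritParams het_rate
#' @param folded Return the mean folded deviation from 0.5 instead of the
#'   raw mean BAF.
#' @return Mean (folded) BAF, or `NA` when no usable het site exists
#'   (the caller retains such calls with a no-evidence flag).
#' @export
mean_baf <- function(call, sites, folded = FALSE) {
  s <- sites_in_call(call, sites)
  s <- s[s$gt == "het" & s$total_reads > 0, , drop = FALSE]
  if (nrow(s) == 0L) return(NA_real_)
  baf <- s$alt_reads / s$total_reads
  if (folded) mean(abs(baf - 0.5)) else mean(baf)
}

sites_in_call <- function(call, sites) {
  assert_columns(sites, c("sample", "chrom", "pos", "gt", "alt_reads",
                          "total_reads"), "sites")
  sites[sites$sample == call$sample &
          as.character(sites$chrom) == as.character(call$chrom) &
          sites$pos >= call$start & sites$pos <= call$end, , drop = FALSE]
}

#' Classify the inheritance of a child CNV call
#'
#' @param child_call Single CNV call (one-row data frame or list).
#' @param father_calls,mother_calls CNV call data frames for the child's
#'   parents (post quality filtering).
#' @param min_fraction Overlap fraction for the same-type interval match.
#' @return One of `"de_novo"`, `"paternal"`, `"maternal"`,
#'   `"biparental"`.
#' @export
classify_inheritance <- function(child_call, father_calls, mother_calls,
                                 min_fraction = 0) {
  in_parent <- function(parent_calls) {
    if (is.null(parent_calls) || nrow(parent_calls) == 0L) return(FALSE)
    same <- parent_calls[parent_calls$type == child_call$type, , drop = FALSE]
    if (nrow(same) == 0L) return(FALSE)
    any(vapply(seq_len(nrow(same)), function(i) {
      overlaps(child_call, same[i, ], min_fraction)
    }, logical(1)))
  }
  pat <- in_parent(father_calls)
  mat <- in_parent(mother_calls)
  if (pat && mat) "biparental" else if (pat) "paternal" else if (mat) "maternal" else "de_novo"
}

#' Run the full exome CNV filtering pipeline
#'
#' Applies, in order: the quality filter, the control-overlap filter, the
#' parent-frequency filter, the SNV allele-evidence false-positive screen
#' (heterozygosity rate for deletions, mean B-allele frequency for
#' duplications), and inheritance classification against the child's own
#' parents. The control, parent-frequency and evidence screens are
#' independent predicates, so their order does not change the retained
#' set; each decision is recorded in a per-call audit table.
#'
#' @param child_calls Child CNV call data frame (`sample`, `chrom`,
#'   `start`, `end`, `type`, `n_exons`, `q_some`, `q_nondiploid`).
#' @param parent_calls Parent CNV call data frame (may be `NULL`).
#' @param controls Control CNV interval data frame (may be `NULL`).
#' @param site_evidence Site allele evidence data frame (may be `NULL`;
#'   calls then carry the no-evidence flag).
#' @param pedigree Data frame mapping `sample` (child) to `father` and
#'   `mother` sample identifiers; required for inheritance
#'   classification.
#' @param min_exons,min_length,min_quality Quality thresholds, see
#'   [quality_filter()].
#' @param max_parents Carrier-parent bound, see
#'   [parent_frequency_filter()].
#' @param het_rate_max Deletions with het rate strictly above this are
#'   removed (default 0.10).
#' @param baf_range Duplications with mean BAF strictly inside this open
#'   interval are removed (default `c(0.4, 0.6)`).
#' @param folded_baf Use the folded BAF deviation (removed when the mean
#'   of `|BAF - 0.5|` is below `(baf_range[2] - baf_range[1]) / 2`).
#' @param min_fraction Overlap fraction used by all interval matches.
#'
#' @return List with `retained` (annotated calls: evidence values,
#'   `no_evidence` flag, `inheritance`) and `audit` (one row per input
#'   call with every filter decision and the removal reason).
#' @export
run_cnv_pipeline <- function(child_calls, parent_calls = NULL,
                             controls = NULL, site_evidence = NULL,
                             pedigree = NULL,
                             min_exons = 3L, min_length = 1000L,
                             min_quality = 90, max_parents = 3L,
                             het_rate_max = 0.10, baf_range = c(0.4, 0.6),
                             folded_baf = FALSE, min_fraction = 0) {
  assert_columns(child_calls, c("sample", "chrom", "start", "end", "type",
                                "n_exons", "q_some", "q_nondiploid"),
                 "child_calls")
  n <- nrow(child_calls)
  len <- child_calls$end - child_calls$start + 1
  pass_quality <- child_calls$n_exons >= min_exons & len >= min_length &
    child_calls$q_some >= min_quality & child_calls$q_nondiploid >= min_quality

  in_controls <- rep(FALSE, n)
  if (!is.null(controls) && nrow(controls) > 0L) {
    hits <- overlap_hits(child_calls, controls, min_fraction)
    in_controls[unique(hits$query_idx)] <- TRUE
  }

  n_carriers <- count_carrier_parents(child_calls, parent_calls, min_fraction)
  pass_parent_freq <- n_carriers <= max_parents

  het <- rep(NA_real_, n)
  baf <- rep(NA_real_, n)
  pass_evidence <- rep(TRUE, n)
  no_evidence <- rep(FALSE, n)
  for (i in seq_len(n)) {
    call <- child_calls[i, ]
    if (is.null(site_evidence) || nrow(site_evidence) == 0L) {
      no_evidence[i] <- TRUE
      next
    }
    if (call$type == "DEL") {
      het[i] <- het_rate(call, site_evidence)
      if (is.na(het[i])) no_evidence[i] <- TRUE
      else pass_evidence[i] <- het[i] <= het_rate_max
    } else {
      baf[i] <- mean_baf(call, site_evidence, folded = folded_baf)
      if (is.na(baf[i])) {
        no_evidence[i] <- TRUE
      } else if (folded_baf) {
        pass_evidence[i] <- baf[i] >= (baf_range[2] - baf_range[1]) / 2
      } else {
        pass_evidence[i] <- !(baf[i] > baf_range[1] & baf[i] < baf_range[2])
      }
    }
  }

  retained_flag <- pass_quality & !in_controls & pass_parent_freq & pass_evidence
  reason <- rep("", n)
  reason[!pass_evidence] <- ifelse(child_calls$type[!pass_evidence] == "DEL",
                                   "het_rate", "mean_baf")
  reason[!pass_parent_freq] <- "parent_frequency"
  reason[in_controls] <- "control_overlap"
  reason[!pass_quality] <- "quality"

  inheritance <- rep(NA_character_, n)
  if (!is.null(pedigree)) {
    assert_columns(pedigree, c("sample", "father", "mother"), "pedigree")
    for (i in which(retained_flag)) {
      ped <- pedigree[pedigree$sample == child_calls$sample[i], , drop = FALSE]
      if (nrow(ped) != 1L) {
        stop("pedigree must map sample ", child_calls$sample[i],
             " to exactly one father and mother", call. = FALSE)
      }
      pc <- if (is.null(parent_calls)) NULL else parent_calls
      fa <- pc[pc$sample == ped$father, , drop = FALSE]
      mo <- pc[pc$sample == ped$mother, , drop = FALSE]
      inheritance[i] <- classify_inheritance(child_calls[i, ], fa, mo,
                                             min_fraction)
    }
  }

  audit <- cbind(child_calls,
                 data.frame(pass_quality = pass_quality,
                            in_controls = in_controls,
                            n_carrier_parents = n_carriers,
                            pass_parent_freq = pass_parent_freq,
                            het_rate = het, mean_baf = baf,
                            no_evidence = no_evidence,
                            pass_evidence = pass_evidence,
                            retained = retained_flag, reason = reason,
                            inheritance = inheritance,
                            stringsAsFactors = FALSE))
  retained <- audit[retained_flag, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, audit = audit)
}
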