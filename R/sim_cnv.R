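#' Describe one simulated CNV event
#'
#' Builds one entry of the `cnv_spec` list consumed by
#' [generate_cnv_calls()]. The `mechanism` field controls whether (and
#' how) the event is an artifact that a specific pipeline filter should
#' remove:
#'
#' * `"none"`: a true event; deletions carry no heterozygous SNVs,
#'   duplications carry het sites whose B-allele frequencies sit on one
#'   side (near 1/3 or 2/3, all alternate alleles in phase on the
#'   duplicated haplotype);
#' * `"het_rate"`: an artifact deletion with het fraction drawn above
#'   0.10;
#' * `"baf"`: an artifact duplication with het-site BAFs near 0.5;
#' * `"control"`: true-like evidence, but the interval is also planted in
#'   the control CNV set;
#' * `"parent_freq"`: true-like evidence, but the interval is copied into
#'   `n_extra_parents` (default 4) unrelated parents;
#' * `"quality"`: true-like evidence, but the call fails the quality
#'   filter through its `q_some`/`q_nondiploid`, `n_exons` or `length`
#'   fields as supplied.
#'
#' @param type `"DEL"` or `"DUP"`.
#' @param length Event length in base pairs.
#' @param n_exons Number of targeted exons reported for the call.
#' @param carrier `"none"` (de novo), `"father"` or `"mother"`; inherited
#'   events are copied into that parent's call set with positional
#'   jitter.
#' @param mechanism Artifact mechanism, see above.
#' @param family Family index (1-based); defaults to round-robin
#'   assignment over the cohort.
#' @param q_some,q_nondiploid Phred-scaled call qualities.
#' @param n_extra_parents Number of unrelated parents the interval is
#'   copied into (used with `mechanism = "parent_freq"`).
#' @return A list of class `cnv_event`.
#' @export
cnv_event <- function(type = c("DEL", "DUP"), length = 5000L,
                      n_exons = NULL, carrier = c("none", "father", "mother"),
                      mechanism = c("none", "het_rate", "baf", "control",
                                    "parent_freq", "quality"),
                      family = NA_integer_, q_some = 99, q_nondiploid = 99,
                      n_extra_parents = 0L) {
  type <- match.arg(type)
  carrier <- match.arg(carrier)
  mechanism <- match.arg(mechanism)
  if (length < 1) stop("CNV length must be positive", call. = FALSE)
  if (mechanism == "het_rate" && type != "DEL") {
    stop("het_rate artifacts are deletions", call. = FALSE)
  }
  if (mechanism == "baf" && type != "DUP") {
    stop("baf artifacts are duplications", call. = FALSE)
  }
  if (mechanism == "parent_freq" && n_extra_parents == 0L) {
    n_extra_parents <- 4L
  }
  if (is.null(n_exons)) n_exons <- max(3L, as.integer(length %/% 1000L))
  structure(list(type = type, length = as.integer(length),
                 n_exons = as.integer(n_exons), carrier = carrier,
                 mechanism = mechanism, family = as.integer(family),
                 q_some = q_some, q_nondiploid = q_nondiploid,
                 n_extra_parents = as.integer(n_extra_parents)),
            class = "cnv_event")
}

#' Simulate exome CNV calls with site allele evidence and known truth
#'
#' Places each event of `config$cnv_spec` on a per-family synthetic
#' chromosome tiled with fixed-width exons (150 bp every 1 kb, 2000
#' exons), simulates SNV allele evidence inside each child call, copies
#' inherited events into the carrier parent's call set with positional
#' jitter of at most `jitter_frac` of the event length, and plants
#' control-set and recurrent-parent copies for the corresponding artifact
#' mechanisms. Site evidence follows a simple binomial read model: depth
#' per site ~ Poisson(`depth_mean`) truncated at 1, B-allele frequency at
#' a het site ~ Binomial(depth, p)/depth with p = 0.5 for diploid signal
#' and p = 1/3 or 2/3 inside a true duplication.
#'
#' @param config A [sim_config()] with a non-empty `cnv_spec`.
#' @param jitter_frac Maximum positional jitter of parental/control
#'   copies, as a fraction of event length (default 0.05).
#' @return List of class `cnv_cohort`: `child_calls`, `parent_calls`,
#'   `controls`, `site_evidence`, `pedigree`, `truth` (per event:
#'   identifiers, mechanism, carrier, `true_event` flag), and `config`.
#' @export
generate_cnv_calls <- function(config, jitter_frac = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$cnv_spec) == 0L) {
    stop("config$cnv_spec is empty: no CNV events to simulate", call. = FALSE)
  }
  set.seed(config$rng_seed + 1L)

  families <- sprintf("F%02d", seq_len(config$n_trios))
  exon_width <- 150L
  exon_stride <- 1000L
  n_exons_map <- 2000L
  chrom_len <- n_exons_map * exon_stride

  pedigree <- data.frame(
    family = families,
    sample = paste0(families, "-C"),
    father = paste0(families, "-F"),
    mother = paste0(families, "-M"),
    stringsAsFactors = FALSE)

  child_calls <- list(); parent_calls <- list(); controls <- list()
  evidence <- list(); truth <- list()
  next_start <- setNames(rep(1L, config$n_trios), families)

  for (k in seq_along(config$cnv_spec)) {
    ev <- config$cnv_spec[[k]]
    if (!inherits(ev, "cnv_event")) {
      stop("cnv_spec entries must be built with cnv_event()", call. = FALSE)
    }
    fam_i <- if (is.na(ev$family)) ((k - 1L) %% config$n_trios) + 1L else ev$family
    if (fam_i < 1L || fam_i > config$n_trios) {
      stop("cnv_event family index out of range: ", fam_i, call. = FALSE)
    }
    fam <- families[fam_i]
    chrom <- paste0("chr_", fam)
    # align the event start to the exon grid, leaving a 10 kb gap
    start <- next_start[fam]
    start <- as.integer(ceiling((start - 1L) / exon_stride) * exon_stride) + 1L
    end <- start + ev$length - 1L
    if (end > chrom_len) {
      stop(sprintf("cnv_spec entry %d falls outside the simulated exon map (end %d > %d)",
                   k, end, chrom_len), call. = FALSE)
    }
    next_start[fam] <- end + 10000L

    child <- pedigree$sample[fam_i]
    call_id <- sprintf("cnv%02d_%s", k, fam)
    child_calls[[k]] <- data.frame(
      call_id = call_id, sample = child, chrom = chrom,
      start = start, end = end, type = ev$type, n_exons = ev$n_exons,
      q_some = ev$q_some, q_nondiploid = ev$q_nondiploid,
      stringsAsFactors = FALSE)

    # --- site allele evidence inside the child call -----------------
    pos <- if (end - start >= 100L) {
      seq.int(start + 50L, end - 50L, by = 300L)
    } else integer(0)
    n_sites <- length(pos)
    if (n_sites > 0L) {
      depth <- sim_depth(n_sites, config$depth_mean)
      gt <- rep("hom_ref", n_sites)
      p_alt <- rep(0, n_sites)
      if (ev$type == "DEL" && ev$mechanism == "het_rate") {
        f <- runif(1, 0.15, 0.40)
        n_het <- max(ceiling(f * n_sites), floor(0.10 * n_sites) + 1L)
        het_idx <- sample.int(n_sites, min(n_het, n_sites))
        gt[het_idx] <- "het"
        p_alt[het_idx] <- 0.5
      } else if (ev$type == "DEL") {
        hom_alt <- rbinom(n_sites, 1L, 0.3) == 1L
        gt[hom_alt] <- "hom_alt"
        p_alt[hom_alt] <- 1
      } else if (ev$type == "DUP" && ev$mechanism == "baf") {
        gt[] <- "het"
        p_alt[] <- 0.5
      } else {
        gt[] <- "het"
        p_alt[] <- sample(c(1 / 3, 2 / 3), 1L)
      }
      alt <- rbinom(n_sites, depth, p_alt)
      evidence[[k]] <- data.frame(
        sample = child, chrom = chrom, pos = pos, gt = gt,
        alt_reads = alt, total_reads = depth, stringsAsFactors = FALSE)
    }

    # --- parental copies (inheritance + recurrent-parent artifacts) --
    jitter <- function() as.integer(round(runif(1, -1, 1) * jitter_frac * ev$length))
    pcopies <- list()
    if (ev$carrier != "none") {
      psample <- if (ev$carrier == "father") pedigree$father[fam_i] else pedigree$mother[fam_i]
      j <- jitter()
      pcopies[[length(pcopies) + 1L]] <- data.frame(
        sample = psample, chrom = chrom, start = start + j, end = end + j,
        type = ev$type, stringsAsFactors = FALSE)
    }
    if (ev$n_extra_parents > 0L) {
      others <- setdiff(seq_len(config$n_trios), fam_i)
      extra <- head(rep(others, 2L), ev$n_extra_parents)
      side <- rep(c("father", "mother"), each = length(others))
      for (m in seq_len(ev$n_extra_parents)) {
        psample <- pedigree[[side[m]]][extra[m]]
        j <- jitter()
        pcopies[[length(pcopies) + 1L]] <- data.frame(
          sample = psample, chrom = chrom, start = start + j, end = end + j,
          type = ev$type, stringsAsFactors = FALSE)
      }
    }
    if (length(pcopies) > 0L) {
      parent_calls[[k]] <- do.call(rbind, pcopies)
    }
    if (ev$mechanism == "control") {
      j <- jitter()
      controls[[k]] <- data.frame(chrom = chrom, start = start + j,
                                  end = end + j, type = ev$type,
                                  stringsAsFactors = FALSE)
    }

    passes_quality <- ev$n_exons >= 3L && ev$length >= 1000L &&
      ev$q_some >= 90 && ev$q_nondiploid >= 90
    truth[[k]] <- data.frame(
      call_id = call_id, family = fam, sample = child, type = ev$type,
      mechanism = ev$mechanism, carrier = ev$carrier,
      is_artifact = ev$mechanism != "none" || !passes_quality,
      true_event = ev$mechanism == "none" && passes_quality,
      stringsAsFactors = FALSE)
  }

  bind <- function(lst, proto) {
    lst <- Filter(Negate(is.null), lst)
    if (length(lst) == 0L) proto else {
      out <- do.call(rbind, lst); rownames(out) <- NULL; out
    }
  }
  structure(list(
    child_calls = bind(child_calls, NULL),
    parent_calls = bind(parent_calls, data.frame(
      sample = character(), chrom = character(), start = integer(),
      end = integer(), type = character())),
    controls = bind(controls, data.frame(
      chrom = character(), start = integer(), end = integer(),
      type = character())),
    site_evidence = bind(evidence, data.frame(
      sample = character(), chrom = character(), pos = integer(),
      gt = character(), alt_reads = integer(), total_reads = integer())),
    pedigree = pedigree,
    truth = bind(truth, NULL),
    config = config), class = "cnv_cohort")
}

#' @export
print.cnv_cohort <- function(x, ...) {
  cat("cnv_cohort:", nrow(x$child_calls), "child calls (",
      sum(x$truth$true_event), "true ), ", nrow(x$parent_calls),
      "parent calls,", nrow(x$controls), "control intervals\n")
  invisible(x)
}

#' Synthetic CNV cohort emulating the published call-set composition
#'
#' A fully synthetic stand-in for a real exome CNV call set: 13 true
#' events (3 de novo, 7 paternal, 3 maternal) mixed with artifacts
#' covering every removal mechanism of the pipeline (a high-het-rate
#' deletion, a diploid-BAF duplication, a control-set overlap, a
#' recurrent-parent event, and calls failing the exon-count, length and
#' quality-score criteria). Running [run_cnv_pipeline()] on this cohort
#' retains exactly the 13 true events with inheritance tallies 3/7/3.
#' The cohort is simulated, not derived from any study data.
#'
#' @param rng_seed Integer seed.
#' @return A `cnv_cohort`, see [generate_cnv_calls()].
#' @export
synthetic_cnv_cohort <- function(rng_seed = 101L) {
  carriers <- c(rep("none", 3L), rep("father", 7L), rep("mother", 3L))
  types <- rep(c("DEL", "DUP"), length.out = 13L)
  true_events <- lapply(seq_len(13L), function(i) {
    cnv_event(type = types[i], length = 4000L + 1000L * (i %% 4L),
              carrier = carriers[i], family = i)
  })
  artifacts <- list(
    cnv_event("DEL", 5000L, mechanism = "het_rate", family = 14L),
    cnv_event("DUP", 5000L, mechanism = "baf", family = 14L),
    cnv_event("DEL", 6000L, mechanism = "control", family = 15L),
    cnv_event("DUP", 6000L, mechanism = "parent_freq", family = 15L),
    cnv_event("DEL", 5000L, mechanism = "quality", q_some = 50, family = 14L),
    cnv_event("DUP", 5000L, n_exons = 2L, mechanism = "quality", family = 15L),
    cnv_event("DEL", 900L, n_exons = 3L, mechanism = "quality", family = 14L))
  cfg <- sim_config(n_trios = 15L, cnv_spec = c(true_events, artifacts),
                    rng_seed = rng_seed)
  generate_cnv_calls(cfg)
}
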