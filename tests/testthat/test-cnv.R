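make_call <- function(sample = "S1", chrom = "chr1", start = 1000L,
                      end = 6000L, type = "DEL", n_exons = 4L,
                      q_some = 95, q_nondiploid = 95) {
  data.frame(sample = sample, chrom = chrom, start = start, end = end,
             type = type, n_exons = n_exons, q_some = q_some,
             q_nondiploid = q_nondiploid, stringsAsFactors = FALSE)
}

make_sites <- function(call, gt, baf = NULL, depth = 50L) {
  n <- length(gt)
  pos <- seq(call$start, call$end, length.out = n)
  alt <- if (is.null(baf)) ifelse(gt == "hom_alt", depth,
                                  ifelse(gt == "het", depth %/% 2L, 0L))
  else as.integer(round(baf * depth))
  data.frame(sample = call$sample, chrom = call$chrom,
             pos = as.integer(pos), gt = gt, alt_reads = alt,
             total_reads = depth, stringsAsFactors = FALSE)
}

test_that("quality filter applies inclusive exon, length and phred bounds", {
  calls <- rbind(
    make_call(start = 1, end = 5000, n_exons = 4, q_some = 95, q_nondiploid = 95),
    make_call(start = 1, end = 999, n_exons = 3, q_some = 95, q_nondiploid = 95),
    make_call(start = 1, end = 1000, n_exons = 3, q_some = 90, q_nondiploid = 90),
    make_call(start = 1, end = 5000, n_exons = 2, q_some = 95, q_nondiploid = 95),
    make_call(start = 1, end = 5000, n_exons = 3, q_some = 89.9, q_nondiploid = 95))
  kept <- quality_filter(calls)
  expect_identical(nrow(kept), 2L)
  dropped <- attr(kept, "dropped")
  expect_setequal(dropped$failed, c("length", "n_exons", "q_some"))
})

test_that("pairwise interval overlap matches the per-base oracle", {
  expect_true(overlaps(list(chrom = "1", start = 100, end = 200),
                       list(chrom = "1", start = 200, end = 300)))
  expect_false(overlaps(list(chrom = "1", start = 100, end = 200),
                        list(chrom = "1", start = 201, end = 300)))
  set.seed(21)
  for (i in 1:200) {
    a <- list(chrom = sample(c("1", "2"), 1),
              start = sample.int(500, 1))
    a$end <- a$start + sample.int(300, 1) - 1L
    b <- list(chrom = sample(c("1", "2"), 1),
              start = sample.int(500, 1))
    b$end <- b$start + sample.int(300, 1) - 1L
    frac <- sample(c(0, 0.25, 0.5, 1), 1)
    expect_identical(overlaps(a, b, frac), oracle_overlaps(a, b, frac),
                     info = sprintf("case %d", i))
  }
})

test_that("control overlap removal drops exactly the overlapping calls", {
  calls <- rbind(make_call(start = 1000, end = 2000),
                 make_call(chrom = "chr9", start = 1000, end = 2000))
  controls <- data.frame(chrom = "chr1", start = 1500, end = 1800,
                         type = "DUP")
  kept <- remove_control_overlaps(calls, controls)
  expect_identical(kept$chrom, "chr9")
  expect_warning(remove_control_overlaps(calls, controls[0, ]), "empty")
})

test_that("parent frequency filter removes calls in more than three parents", {
  call <- make_call(start = 1000, end = 2000)
  parents <- function(n) do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(sample = paste0("P", i), chrom = "chr1", start = 1100,
               end = 1900, type = "DEL", stringsAsFactors = FALSE)
  }))
  expect_identical(nrow(parent_frequency_filter(call, parents(3))), 1L)
  expect_identical(nrow(parent_frequency_filter(call, parents(4))), 0L)
  # same interval, opposite type does not count
  p <- parents(4); p$type <- "DUP"
  expect_identical(nrow(parent_frequency_filter(call, p)), 1L)
})

test_that("het rate arithmetic and the strict 10% boundary", {
  call <- make_call()
  s10_2 <- make_sites(call, c(rep("het", 2), rep("hom_ref", 8)))
  expect_equal(het_rate(call, s10_2), 0.2)
  s10_1 <- make_sites(call, c("het", rep("hom_ref", 9)))
  expect_equal(het_rate(call, s10_1), 0.1)
  out <- run_cnv_pipeline(call, site_evidence = s10_1)
  expect_identical(nrow(out$retained), 1L)       # 0.1 is not above 10%
  out2 <- run_cnv_pipeline(call, site_evidence = s10_2)
  expect_identical(nrow(out2$retained), 0L)
  expect_identical(out2$audit$reason, "het_rate")
  # zero sites -> undefined, retained with the no-evidence flag
  expect_true(is.na(het_rate(call, s10_1[0, ])))
  out3 <- run_cnv_pipeline(call, site_evidence = s10_1[0, ])
  expect_identical(nrow(out3$retained), 1L)
  expect_true(out3$retained$no_evidence)
})

test_that("duplication mean BAF screen, including the symmetric caveat", {
  call <- make_call(type = "DUP")
  baf_sites <- function(baf) make_sites(call, rep("het", length(baf)),
                                        baf = baf, depth = 100L)
  expect_equal(mean_baf(call, baf_sites(c(0.33, 0.35, 0.65))),
               mean(c(0.33, 0.35, 0.65)))
  removed <- function(baf) {
    nrow(run_cnv_pipeline(call, site_evidence = baf_sites(baf))$retained) == 0L
  }
  expect_true(removed(c(0.33, 0.35, 0.65)))   # mean 0.443
  expect_true(removed(c(0.30, 0.70, 0.32)))   # mean 0.44
  expect_true(removed(c(0.30, 0.70, 0.66, 0.34)))  # mean 0.5: symmetric case
  expect_true(removed(c(0.33, 0.67)))              # mean 0.5: symmetric case
  expect_false(removed(0.35))                 # single site, retained
  # folded mode separates split BAFs from genuinely diploid signal
  split_sites <- baf_sites(c(0.33, 0.67, 0.66, 0.34))
  diploid_sites <- baf_sites(c(0.48, 0.52, 0.50, 0.49))
  out_split <- run_cnv_pipeline(call, site_evidence = split_sites,
                                folded_baf = TRUE)
  expect_identical(nrow(out_split$retained), 1L)
  out_diploid <- run_cnv_pipeline(call, site_evidence = diploid_sites,
                                  folded_baf = TRUE)
  expect_identical(nrow(out_diploid$retained), 0L)
})

test_that("inheritance classification covers all four configurations", {
  child <- make_call(sample = "C", type = "DUP")
  match_call <- function(s) data.frame(sample = s, chrom = "chr1",
                                       start = 1200, end = 5800,
                                       type = "DUP", stringsAsFactors = FALSE)
  none <- match_call("F")[0, ]
  expect_identical(classify_inheritance(child, match_call("F"), none),
                   "paternal")
  expect_identical(classify_inheritance(child, none, match_call("M")),
                   "maternal")
  expect_identical(classify_inheritance(child, match_call("F"),
                                        match_call("M")), "biparental")
  expect_identical(classify_inheritance(child, none, none), "de_novo")
  # same interval but opposite type is not inheritance
  del <- match_call("F"); del$type <- "DEL"
  expect_identical(classify_inheritance(child, del, none), "de_novo")
})

test_that("screen predicates are independent: filter order cannot matter", {
  sc <- synthetic_cnv_cohort(rng_seed = 7)
  full <- run_cnv_pipeline(sc$child_calls, sc$parent_calls, sc$controls,
                           sc$site_evidence, sc$pedigree)
  # applying the control and parent screens to pre-filtered input leaves
  # the retained set unchanged
  q <- quality_filter(sc$child_calls)
  a <- remove_control_overlaps(q, sc$controls)
  b <- parent_frequency_filter(a, sc$parent_calls)
  c2 <- parent_frequency_filter(q, sc$parent_calls)
  d <- remove_control_overlaps(c2, sc$controls)
  expect_setequal(paste(b$sample, b$start), paste(d$sample, d$start))
  rerun <- run_cnv_pipeline(full$retained[, names(sc$child_calls)],
                            sc$parent_calls, sc$controls, sc$site_evidence,
                            sc$pedigree)
  expect_identical(nrow(rerun$retained), nrow(full$retained))
})

test_that("the pipeline recovers planted CNV truth on simulated cohorts", {
  sc <- synthetic_cnv_cohort(rng_seed = 3)
  out <- run_cnv_pipeline(sc$child_calls, sc$parent_calls, sc$controls,
                          sc$site_evidence, sc$pedigree)
  truth <- sc$truth
  expect_setequal(out$retained$call_id, truth$call_id[truth$true_event])
  inh <- out$retained$inheritance
  carrier <- truth$carrier[match(out$retained$call_id, truth$call_id)]
  expect_identical(unname(inh[carrier == "father"]),
                   rep("paternal", sum(carrier == "father")))
  expect_identical(unname(inh[carrier == "mother"]),
                   rep("maternal", sum(carrier == "mother")))
  expect_identical(unname(inh[carrier == "none"]),
                   rep("de_novo", sum(carrier == "none")))
})

test_that("an all-artifact cohort filters to an empty call set", {
  spec <- list(cnv_event("DEL", 5000, mechanism = "het_rate"),
               cnv_event("DUP", 5000, mechanism = "baf"),
               cnv_event("DEL", 900, n_exons = 3, mechanism = "quality"))
  sc <- generate_cnv_calls(sim_config(n_trios = 3, cnv_spec = spec,
                                      rng_seed = 8))
  out <- run_cnv_pipeline(sc$child_calls, sc$parent_calls, sc$controls,
                          sc$site_evidence, sc$pedigree)
  expect_identical(nrow(out$retained), 0L)
})

test_that("XHMM-style and BED round trips preserve calls and coordinates", {
  sc <- synthetic_cnv_cohort(rng_seed = 2)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_cnv_calls(sc$child_calls, tmp)
  back <- read_cnv_calls(tmp)
  expect_identical(back$start, sc$child_calls$start)
  expect_identical(back$end, sc$child_calls$end)
  expect_identical(back$type, sc$child_calls$type)
  # BED is 0-based half-open on disk; round trip through rtracklayer
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(sprintf("%s\t%d\t%d\t%s", "chr7", 999L, 2000L, "DEL"), bed)
  ctl <- read_controls_bed(bed)
  expect_identical(ctl$start, 1000L)
  expect_identical(ctl$end, 2000L)
})
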