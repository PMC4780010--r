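#' Classify variants by maximum population allele frequency
#'
#' Frequency classes follow the conventional exome-study bands: `common`
#' when the maximum minor allele frequency across reference databases
#' exceeds 5%, `rare` for MAF in the closed interval \[1%, 5%\],
#' `very_rare` below 1% (but present in a database), and `novel` when the
#' variant is absent from the databases (`NA`). Interior boundaries are
#' assigned to `rare`.
#'
#' @param maf_max Numeric vector of maximum MAFs in \[0, 0.5\]; `NA` means
#'   the variant was not found in any database.
#' @return Character vector: `"common"`, `"rare"`, `"very_rare"` or
#'   `"novel"`.
#' @examples
#' classify_frequency(c(0.06, 0.05, 0.01, 0.0099, NA))
#' @export
classify_frequency <- function(maf_max) {
  bad <- !is.na(maf_max) & (maf_max < 0 | maf_max > 0.5)
  if (any(bad)) {
    stop("maf_max outside [0, 0.5]: ",
         paste(format(maf_max[bad]), collapse = ", "), call. = FALSE)
  }
  out <- rep("novel", length(maf_max))
  out[!is.na(maf_max) & maf_max > 0.05] <- "common"
  out[!is.na(maf_max) & maf_max >= 0.01 & maf_max <= 0.05] <- "rare"
  out[!is.na(maf_max) & maf_max < 0.01] <- "very_rare"
  out
}

#' Classify variant consequence by predicted impact
#'
#' Nonsense and splice-site variants are HIGH impact, missense MODERATE;
#' everything else (synonymous, other) is `other`.
#'
#' @param consequence Character vector of consequence classes (see
#'   [consequence_codes()]).
#' @return Character vector: `"HIGH"`, `"MODERATE"` or `"other"`.
#' @export
classify_impact <- function(consequence) {
  bad <- !consequence %in% consequence_codes()
  if (any(bad)) {
    stop("unknown consequence value(s): ",
         paste(unique(consequence[bad]), collapse = ", "),
         "; accepted: ", paste(consequence_codes(), collapse = ", "),
         call. = FALSE)
  }
  out <- rep("other", length(consequence))
  out[consequence %in% c("nonsense", "splice_site")] <- "HIGH"
  out[consequence == "missense"] <- "MODERATE"
  out
}

#' Three-rule triage of annotated trio variants
#'
#' Extracts the three candidate variant classes from annotated trio
#' records:
#'
#' 1. `DN_MODHIGH` - de novo, moderate or high impact: child carries the
#'    alternate allele while both parents are homozygous reference;
#' 2. `RARE_RECESSIVE` - rare missense homozygous in the child at loci
#'    where both parents are heterozygous;
#' 3. `VRARE_HIGH_HET` - very rare or novel, high impact (nonsense or
#'    splice site), heterozygous in the child and inherited from exactly
#'    one heterozygous parent.
#'
#' All rules require every trio member to have read depth of at least
#' `min_depth` at the site and the gene to be in the brain-expressed set.
#' Records with a missing genotype in any tested member are skipped and
#' counted in the skip report. Rule 1 imposes no frequency filter.
#'
#' @param records Data frame of trio variant records with columns
#'   `family`, `chrom`, `pos`, `gene`, `consequence`, `maf_max`, `band`,
#'   `gt_child`, `gt_father`, `gt_mother`, `dp_child`, `dp_father`,
#'   `dp_mother` (as produced by [generate_trio_cohort()],
#'   [read_trio_vcf()] or [as_trio_records()]).
#' @param brain_genes Character vector of brain-expressed gene symbols;
#'   all rules are restricted to these genes.
#' @param min_depth Minimum read depth required in all three members
#'   (default 10).
#'
#' @return An object of class `triage_result`: list with `rules` (named
#'   list of three data frames `DN_MODHIGH`, `RARE_RECESSIVE`,
#'   `VRARE_HIGH_HET`) and `skipped` (data frame of skip reasons and
#'   counts).
#' @export
triage <- function(records, brain_genes, min_depth = 10L) {
  assert_columns(records,
                 c("family", "chrom", "pos", "gene", "consequence",
                   "maf_max", "band", "gt_child", "gt_father", "gt_mother",
                   "dp_child", "dp_father", "dp_mother"),
                 "records")
  if (nrow(records) == 0L) {
    empty <- records[0, , drop = FALSE]
    return(structure(list(
      rules = list(DN_MODHIGH = empty, RARE_RECESSIVE = empty,
                   VRARE_HIGH_HET = empty),
      skipped = data.frame(reason = character(), n = integer())),
      class = "triage_result"))
  }
  gt_ok <- records$gt_child != "missing" &
    records$gt_father != "missing" & records$gt_mother != "missing"
  usable <- records[gt_ok, , drop = FALSE]

  impact <- classify_impact(usable$consequence)
  freq <- classify_frequency(usable$maf_max)
  depth_ok <- !is.na(usable$dp_child) & usable$dp_child >= min_depth &
    !is.na(usable$dp_father) & usable$dp_father >= min_depth &
    !is.na(usable$dp_mother) & usable$dp_mother >= min_depth
  in_brain <- usable$gene %in% brain_genes
  base_ok <- depth_ok & in_brain

  rule1 <- base_ok &
    usable$gt_child %in% c("het", "hom_alt") &
    usable$gt_father == "hom_ref" & usable$gt_mother == "hom_ref" &
    impact %in% c("MODERATE", "HIGH")
  rule2 <- base_ok &
    usable$gt_child == "hom_alt" &
    usable$gt_father == "het" & usable$gt_mother == "het" &
    impact == "MODERATE" & freq == "rare"
  one_parent_het <- (usable$gt_father == "het" & usable$gt_mother == "hom_ref") |
    (usable$gt_mother == "het" & usable$gt_father == "hom_ref")
  rule3 <- base_ok &
    usable$gt_child == "het" & one_parent_het &
    impact == "HIGH" & freq %in% c("very_rare", "novel")

  skipped <- data.frame(reason = "missing genotype in trio member",
                        n = sum(!gt_ok), stringsAsFactors = FALSE)
  skipped <- skipped[skipped$n > 0L, , drop = FALSE]

  pick <- function(sel) {
    out <- usable[sel, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  structure(list(rules = list(DN_MODHIGH = pick(rule1),
                              RARE_RECESSIVE = pick(rule2),
                              VRARE_HIGH_HET = pick(rule3)),
                 skipped = skipped),
            class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  n <- vapply(x$rules, nrow, integer(1))
  cat("triage_result:", paste(names(n), n, sep = " = ", collapse = ", "),
      if (nrow(x$skipped)) sprintf("(%d record(s) skipped)", sum(x$skipped$n)) else "",
      "\n")
  invisible(x)
}

#' Major cytogenetic band
#'
#' Strips the sub-band suffix after the first dot, so `"19p13.2"`,
#' `"19p13.11"` and `"19p13.3"` all aggregate to `"19p13"`.
#'
#' @param band Character vector of cytogenetic band labels matching
#'   `<chrom><arm><digits>[.<digits>]`.
#' @return Character vector of major band labels.
#' @export
major_band <- function(band) {
  ok <- grepl("^([0-9]{1,2}|X|Y)[pq][0-9]+(\\.[0-9]+)?$", band)
  if (any(!ok)) {
    stop("malformed cytogenetic band label(s): ",
         paste(unique(band[!ok]), collapse = ", "), call. = FALSE)
  }
  sub("\\..*$", "", band)
}

#' Recurrence summary of triaged variant records
#'
#' Summarizes a set of variant records (typically one triage rule's
#' output) per gene, per major cytogenetic band, and per family. Two
#' recurrence flags used later as integration evidence are computed per
#' gene: `sv2c` (the same variant, identified by chromosome and position,
#' observed in at least two families) and `two_vsc` (at least two distinct
#' variants of the gene in one family).
#'
#' @param records Data frame of variant records (columns `family`,
#'   `chrom`, `pos`, `gene`, `band`), e.g. one element of
#'   `triage(...)$rules`.
#' @return List of data frames: `genes` (gene, n_variants, n_families,
#'   max_per_family, sv2c, two_vsc), `bands` (major_band, n_families),
#'   `families` (family, n_variants). Records whose band label cannot be
#'   parsed are dropped from the band table with a warning.
#' @export
recurrence_summary <- function(records) {
  assert_columns(records, c("family", "chrom", "pos", "gene", "band"),
                 "records")
  if (nrow(records) == 0L) {
    return(list(
      genes = data.frame(gene = character(), n_variants = integer(),
                         n_families = integer(), max_per_family = integer(),
                         sv2c = logical(), two_vsc = logical()),
      bands = data.frame(major_band = character(), n_families = integer()),
      families = data.frame(family = character(), n_variants = integer())))
  }
  variant_id <- paste(records$chrom, records$pos, sep = ":")

  genes <- do.call(rbind, lapply(split(seq_len(nrow(records)), records$gene),
                                 function(i) {
    fam <- records$family[i]
    vid <- variant_id[i]
    per_fam <- table(fam)
    fam_per_variant <- tapply(fam, vid, function(f) length(unique(f)))
    data.frame(gene = records$gene[i][1L],
               n_variants = length(i),
               n_families = length(unique(fam)),
               max_per_family = as.integer(max(per_fam)),
               sv2c = any(fam_per_variant >= 2L),
               two_vsc = any(tapply(vid, fam, function(v) length(unique(v))) >= 2L),
               stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL

  parseable <- grepl("^([0-9]{1,2}|X|Y)[pq][0-9]+(\\.[0-9]+)?$", records$band)
  if (any(!parseable)) {
    warning("dropping ", sum(!parseable),
            " record(s) with unparseable band label from the band table")
  }
  br <- records[parseable, , drop = FALSE]
  if (nrow(br) > 0L) {
    mb <- major_band(br$band)
    n_fam <- tapply(br$family, mb, function(f) length(unique(f)))
    bands <- data.frame(major_band = names(n_fam),
                        n_families = as.integer(n_fam),
                        stringsAsFactors = FALSE)
  } else {
    bands <- data.frame(major_band = character(), n_families = integer())
  }
  bands <- bands[order(-bands$n_families, bands$major_band), , drop = FALSE]
  rownames(bands) <- NULL

  fam_tab <- table(records$family)
  families <- data.frame(family = names(fam_tab),
                         n_variants = as.integer(fam_tab),
                         stringsAsFactors = FALSE)
  list(genes = genes, bands = bands, families = families)
}
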