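#' Packaged table of 26 published de novo single-nucleotide variants
#'
#' Loads the packaged transcription of a published table of 26 de novo
#' SNVs found in 25 brain-expressed genes across an ADHD trio cohort,
#' with cytogenetic band, family identifier, printed impact annotation
#' and frequency class.
#'
#' @param path Optional path to an alternative TSV with the same columns.
#' @return Data frame with columns `chrom`, `pos`, `rsid`, `band`,
#'   `gene`, `impact`, `family`, `frequency`.
#' @seealso [as_trio_records()] to embed each row in a synthetic trio
#'   variant record.
#' @export
load_denovo_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "denovo_snv_fixture.tsv",
                        package = "trionet", mustWork = TRUE)
  }
  read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

#' Packaged table of 30 genes with two evidence categories
#'
#' Loads the packaged transcription of a published table of 30 genes
#' supported by at least two evidence categories (public CNV studies,
#' public GWAS SNPs, exome CNVs, exome SNVs), including the recurrence
#' codes `sv2c` (same variant in 2 children), `2vsc` (2 variants in the
#' same child) and `3vsc` (3 variants in the same child).
#'
#' @param path Optional path to an alternative TSV with the same columns.
#' @return Data frame with columns `gene`, `public_cnv`, `public_snp`,
#'   `exome_cnv`, `exome_snv`, `band`.
#' @seealso [as_evidence_matrix()]
#' @export
load_two_evidence_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "two_evidence_fixture.tsv",
                        package = "trionet", mustWork = TRUE)
  }
  read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

# Printed impact annotations -> consequence codes.
impact_to_consequence <- c(
  "NON SYNONYMOUS CODING" = "missense",
  "STOP GAINED" = "nonsense",
  "STOP LOST" = "nonsense",
  "SPLICE SITE ACCEPTOR" = "splice_site",
  "SPLICE SITE DONOR" = "splice_site",
  "SYNONYMOUS CODING" = "synonymous")

# Representative maximum MAF for each printed frequency class; chosen so
# classify_frequency() round-trips to the printed class.
frequency_to_maf <- c(common = 0.25, rare = 0.03, "very rare" = 0.005)

#' Embed a printed de novo variant table as trio variant records
#'
#' Turns each row of a published de novo SNV table (see
#' [load_denovo_table()]) into a full trio variant record with the de
#' novo genotype pattern: child heterozygous, both parents homozygous
#' reference, all depths at `depth`. The printed impact annotation is
#' mapped to a consequence code and the printed frequency class to a
#' representative maximum MAF that reproduces the class under
#' [classify_frequency()] (`novel` becomes `NA`).
#'
#' @param table Data frame from [load_denovo_table()].
#' @param depth Read depth assigned to all three members (default 40).
#' @return Trio variant record data frame accepted by [triage()].
#' @export
as_trio_records <- function(table, depth = 40L) {
  assert_columns(table, c("chrom", "pos", "rsid", "band", "gene", "impact",
                          "family", "frequency"), "table")
  if (nrow(table) == 0L) {
    return(data.frame(family = character(), chrom = character(),
                      pos = integer(), rsid = character(), ref = character(),
                      alt = character(), gene = character(),
                      consequence = character(), maf_max = numeric(),
                      band = character(), gt_child = character(),
                      gt_father = character(), gt_mother = character(),
                      dp_child = integer(), dp_father = integer(),
                      dp_mother = integer(), stringsAsFactors = FALSE))
  }
  consequence <- unname(impact_to_consequence[table$impact])
  freq_known <- table$frequency %in% c(names(frequency_to_maf), "novel")
  bad <- which(is.na(consequence) | !freq_known | is.na(table$gene) |
                 table$gene == "" | is.na(suppressWarnings(as.integer(table$pos))))
  if (length(bad) > 0L) {
    stop("malformed fixture row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  maf <- unname(frequency_to_maf[table$frequency])
  data.frame(
    family = table$family, chrom = table$chrom,
    pos = as.integer(table$pos), rsid = table$rsid,
    ref = "A", alt = "G", gene = table$gene, consequence = consequence,
    maf_max = maf, band = table$band,
    gt_child = "het", gt_father = "hom_ref", gt_mother = "hom_ref",
    dp_child = as.integer(depth), dp_father = as.integer(depth),
    dp_mother = as.integer(depth), stringsAsFactors = FALSE)
}

#' Decoy records violating one de novo triage criterion each
#'
#' Builds inherited and otherwise disqualified companions for a set of de
#' novo records, to exercise the triage filters: a record with parental
#' depth 9, a synonymous record, a record in a gene absent from the
#' brain-expressed set, and an inherited record (father heterozygous).
#'
#' @param records Trio variant records (e.g. from [as_trio_records()]).
#' @return Data frame of decoy records, one per violation type.
#' @export
table_decoy_records <- function(records) {
  stopifnot(nrow(records) >= 1L)
  base <- records[rep(seq_len(min(4L, nrow(records))), length.out = 4L), ,
                  drop = FALSE]
  base$pos <- base$pos + 1L
  base$rsid <- "."
  low_depth <- base[1L, ]; low_depth$dp_father <- 9L
  syn <- base[2L, ]; syn$consequence <- "synonymous"
  non_brain <- base[3L, ]; non_brain$gene <- "DECOY_NOT_IN_BRAIN"
  inherited <- base[4L, ]; inherited$gt_father <- "het"
  out <- rbind(low_depth, syn, non_brain, inherited)
  rownames(out) <- NULL
  out
}

#' Evidence matrix from a printed two-evidence gene table
#'
#' Converts the printed category cells (`yes`, `no`, `sv2c`, `2vsc`,
#' `3vsc`) of a two-evidence gene table (see
#' [load_two_evidence_table()]) into the logical evidence matrix
#' consumed by [select_seeds()]: a category is flagged when its cell is
#' anything but `no`; the `sv2c` annotation is set when any cell reads
#' `sv2c`, and `two_vsc` when any cell reads `2vsc` or `3vsc`.
#'
#' @param table Data frame from [load_two_evidence_table()].
#' @return An `evidence_matrix` data frame, see
#'   [build_evidence_matrix()].
#' @export
as_evidence_matrix <- function(table) {
  assert_columns(table, c("gene", "public_cnv", "public_snp", "exome_cnv",
                          "exome_snv"), "table")
  cat_cols <- c("public_cnv", "public_snp", "exome_cnv", "exome_snv")
  if (nrow(table) == 0L) {
    return(build_evidence_matrix())
  }
  cells <- as.matrix(table[, cat_cols])
  allowed <- c("no", "yes", "sv2c", "2vsc", "3vsc")
  bad <- which(apply(cells, 1L, function(r) any(!r %in% allowed)))
  if (length(bad) > 0L) {
    stop("malformed fixture row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(gene = table$gene,
                    public_cnv = cells[, "public_cnv"] != "no",
                    public_snp = cells[, "public_snp"] != "no",
                    exome_cnv = cells[, "exome_cnv"] != "no",
                    exome_snv = cells[, "exome_snv"] != "no",
                    sv2c = apply(cells, 1L, function(r) any(r == "sv2c")),
                    two_vsc = apply(cells, 1L, function(r) any(r %in% c("2vsc", "3vsc"))),
                    n_families = NA_integer_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("evidence_matrix", class(out))
  out
}
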