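#' Write a trio cohort as minimal per-family VCF files
#'
#' One VCF per family with three sample columns (child, father, mother;
#' named `<family>-C`, `<family>-F`, `<family>-M`), `GT` and `DP` FORMAT
#' fields, and INFO keys `GENE`, `CSQ`, `MAFMAX` (omitted for novel
#' variants) and `BAND`.
#'
#' @param cohort A `trio_cohort` or its `variants` data frame.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the written files.
#' @export
write_trio_vcf <- function(cohort, dir) {
  v <- if (inherits(cohort, "trio_cohort")) cohort$variants else cohort
  assert_columns(v, c("family", "chrom", "pos", "rsid", "ref", "alt",
                      "gene", "consequence", "maf_max", "band",
                      "gt_child", "gt_father", "gt_mother",
                      "dp_child", "dp_father", "dp_mother"), "variants")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               missing = "./.")
  paths <- vapply(unique(v$family), function(fam) {
    d <- v[v$family == fam, , drop = FALSE]
    d <- d[order(d$chrom, d$pos), , drop = FALSE]
    info <- paste0("GENE=", d$gene, ";CSQ=", d$consequence,
                   ifelse(is.na(d$maf_max), "",
                          paste0(";MAFMAX=", format(d$maf_max, digits = 10,
                                                    scientific = FALSE))),
                   ";BAND=", d$band)
    body <- paste(d$chrom, d$pos, d$rsid, d$ref, d$alt, ".", "PASS", info,
                  "GT:DP",
                  paste0(gt_code[d$gt_child], ":", d$dp_child),
                  paste0(gt_code[d$gt_father], ":", d$dp_father),
                  paste0(gt_code[d$gt_mother], ":", d$dp_mother),
                  sep = "\t")
    header <- c(
      "##fileformat=VCFv4.2",
      "##source=trionet",
      "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
      "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
      "##INFO=<ID=MAFMAX,Number=1,Type=Float,Description=\"Maximum population MAF\">",
      "##INFO=<ID=BAND,Number=1,Type=String,Description=\"Cytogenetic band\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0(fam, "-C"), paste0(fam, "-F"),
            paste0(fam, "-M"), sep = "\t"))
    path <- file.path(dir, paste0(fam, ".vcf"))
    writeLines(c(header, body), path)
    path
  }, character(1))
  invisible(unname(paths))
}

#' Read per-family trio VCF files into a variant record table
#'
#' Reads VCFs written by [write_trio_vcf()] (or any VCF with three
#' samples ordered child, father, mother, `GT`/`DP` FORMAT fields and
#' INFO keys `GENE`, `CSQ`, `MAFMAX`, `BAND`). Parsing is done with the
#' vcfR package.
#'
#' @param paths Character vector of VCF file paths (one family each).
#' @param families Optional family identifiers; defaults to the file
#'   base names without extension.
#' @return A `trio_cohort`-style list with a `variants` data frame.
#' @export
read_trio_vcf <- function(paths, families = NULL) {
  if (is.null(families)) {
    families <- sub("\\.vcf(\\.gz)?$", "", basename(paths))
  }
  stopifnot(length(families) == length(paths))
  gt_decode <- c("0/0" = "hom_ref", "0/1" = "het", "1/0" = "het",
                 "1/1" = "hom_alt", "./." = "missing",
                 "0|0" = "hom_ref", "0|1" = "het", "1|0" = "het",
                 "1|1" = "hom_alt", ".|." = "missing")
  tables <- lapply(seq_along(paths), function(i) {
    vcf <- vcfR::read.vcfR(paths[i], verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
    if (ncol(gt) != 3L) {
      stop("expected 3 samples (child, father, mother) in ", paths[i],
           call. = FALSE)
    }
    info1 <- function(key) {
      val <- vcfR::extract.info(vcf, element = key)
      if (is.null(val)) rep(NA_character_, nrow(fix)) else val
    }
    decode <- function(x) {
      out <- unname(gt_decode[x])
      out[is.na(out)] <- "missing"
      out
    }
    maf <- suppressWarnings(as.numeric(info1("MAFMAX")))
    data.frame(
      family = families[i], chrom = fix$CHROM, pos = as.integer(fix$POS),
      rsid = fix$ID, ref = fix$REF, alt = fix$ALT,
      gene = info1("GENE"), consequence = info1("CSQ"),
      maf_max = maf, band = info1("BAND"),
      gt_child = decode(gt[, 1L]), gt_father = decode(gt[, 2L]),
      gt_mother = decode(gt[, 3L]),
      dp_child = as.integer(dp[, 1L]), dp_father = as.integer(dp[, 2L]),
      dp_mother = as.integer(dp[, 3L]), stringsAsFactors = FALSE)
  })
  variants <- do.call(rbind, tables)
  rownames(variants) <- NULL
  structure(list(variants = variants, families = families),
            class = "trio_cohort")
}

#' Write CNV calls as an XHMM-style table
#'
#' Columns `SAMPLE`, `CNV`, `INTERVAL` (`chr:start-end`, 1-based
#' closed), `NUM_TARGETS`, `Q_SOME`, `Q_NON_DIPLOID`.
#'
#' @param calls CNV call data frame (see [quality_filter()]).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_cnv_calls <- function(calls, path) {
  assert_columns(calls, c("sample", "chrom", "start", "end", "type",
                          "n_exons", "q_some", "q_nondiploid"), "calls")
  out <- data.frame(SAMPLE = calls$sample, CNV = calls$type,
                    INTERVAL = sprintf("%s:%d-%d", calls$chrom,
                                       calls$start, calls$end),
                    NUM_TARGETS = calls$n_exons, Q_SOME = calls$q_some,
                    Q_NON_DIPLOID = calls$q_nondiploid)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an XHMM-style CNV call table
#'
#' @param path TSV with columns `SAMPLE`, `CNV`, `INTERVAL`
#'   (`chr:start-end`), `NUM_TARGETS`, `Q_SOME`, `Q_NON_DIPLOID`.
#' @return CNV call data frame with 1-based closed coordinates.
#' @export
read_cnv_calls <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  assert_columns(raw, c("SAMPLE", "CNV", "INTERVAL", "NUM_TARGETS",
                        "Q_SOME", "Q_NON_DIPLOID"), "CNV table")
  m <- regmatches(raw$INTERVAL,
                  regexec("^(.+):([0-9]+)-([0-9]+)$", raw$INTERVAL))
  bad <- which(vapply(m, length, integer(1)) != 4L)
  if (length(bad) > 0L) {
    stop("malformed INTERVAL at row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  data.frame(sample = raw$SAMPLE,
             chrom = vapply(m, `[`, character(1), 2L),
             start = as.integer(vapply(m, `[`, character(1), 3L)),
             end = as.integer(vapply(m, `[`, character(1), 4L)),
             type = raw$CNV, n_exons = raw$NUM_TARGETS,
             q_some = raw$Q_SOME, q_nondiploid = raw$Q_NON_DIPLOID,
             stringsAsFactors = FALSE)
}

#' Read control CNV intervals from a BED file
#'
#' BED files are 0-based half-open on disk; the returned coordinates are
#' 1-based closed, as used throughout the package. Parsing is delegated
#' to rtracklayer.
#'
#' @param path BED file path; the name field, when present, is taken as
#'   the CNV type.
#' @return Data frame `chrom`, `start`, `end`, `type`.
#' @export
read_controls_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  type <- if (!is.null(gr$name)) as.character(gr$name) else NA_character_
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             type = type, stringsAsFactors = FALSE)
}

#' Read a protein-protein interaction edge list
#'
#' @param path TSV with three columns: `node_a`, `node_b`,
#'   `evidence_count`.
#' @return Edge data frame accepted by [build_graph()].
#' @export
read_ppi_edges <- function(path) {
  edges <- read.delim(path, stringsAsFactors = FALSE)
  assert_columns(edges, c("node_a", "node_b", "evidence_count"), "edges")
  bad <- which(is.na(edges$evidence_count) | edges$node_a == "" |
                 edges$node_b == "")
  if (length(bad) > 0L) {
    stop("malformed edge record at line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  edges
}
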