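#' Genes overlapping a genomic region
#'
#' Returns every gene whose interval overlaps the region by at least one
#' base. Coordinates are 1-based closed.
#'
#' @param region List or one-row data frame with `chrom`, `start`, `end`.
#' @param genes Gene model data frame with columns `symbol`, `chrom`,
#'   `start`, `end` (optionally `band`, `olfactory`).
#' @return Character vector of gene symbols (unique, input order).
#' @export
genes_in_region <- function(region, genes) {
  assert_columns(genes, c("symbol", "chrom", "start", "end"), "genes")
  region_df <- data.frame(chrom = region$chrom, start = region$start,
                          end = region$end)
  hits <- overlap_hits(region_df, genes)
  unique(genes$symbol[hits$subject_idx])
}

#' Restrict a gene set to brain-expressed genes
#'
#' A gene is considered brain-expressed when its maximum RPKM across all
#' brain areas and samples is at least `min_rpkm` (default 1, inclusive).
#' Genes absent from the expression table are treated as not expressed
#' and reported in the `"missing"` attribute of the result.
#'
#' @param genes Character vector of gene symbols.
#' @param expression Data frame with columns `gene` and `max_rpkm`.
#' @param min_rpkm Expression threshold in RPKM (default 1).
#' @return Character vector of the genes passing the filter, with
#'   attribute `missing` listing genes absent from the table.
#' @export
brain_filter <- function(genes, expression, min_rpkm = 1) {
  assert_columns(expression, c("gene", "max_rpkm"), "expression")
  if (any(expression$max_rpkm < 0, na.rm = TRUE)) {
    stop("RPKM values must be non-negative", call. = FALSE)
  }
  rpkm <- expression$max_rpkm[match(genes, expression$gene)]
  missing <- genes[is.na(rpkm)]
  kept <- genes[!is.na(rpkm) & rpkm >= min_rpkm]
  attr(kept, "missing") <- missing
  kept
}

#' Remove olfactory receptor genes from a gene set
#'
#' Olfactory receptor genes are dropped to avoid their well-known bias in
#' functional enrichment. Detection uses the `olfactory` flag of the gene
#' models when provided, plus the OR-family symbol pattern
#' (`OR` followed by a digit, e.g. `OR8K3`).
#'
#' @param genes Character vector of gene symbols.
#' @param gene_models Optional gene model data frame with columns
#'   `symbol` and `olfactory`.
#' @param pattern Regular expression identifying OR-family symbols.
#' @return Character vector with olfactory receptors removed.
#' @examples
#' remove_olfactory(c("OR8K3", "CYFIP2"))
#' @export
remove_olfactory <- function(genes, gene_models = NULL,
                             pattern = "^OR[0-9]") {
  olf <- grepl(pattern, genes)
  if (!is.null(gene_models)) {
    assert_columns(gene_models, c("symbol", "olfactory"), "gene_models")
    flagged <- gene_models$symbol[gene_models$olfactory]
    olf <- olf | genes %in% flagged
  }
  genes[!olf]
}

#' Build the gene-by-evidence-category matrix
#'
#' Merges exome SNV hits, exome CNV gene hits and public SNP/CNV gene
#' lists into one row per gene with four category flags and two
#' recurrence annotations: `sv2c` (same variant observed in two or more
#' families, or the gene hit by CNVs in two or more families) and
#' `two_vsc` (two or more distinct variants of the gene in one child).
#' All sources are expected to be brain-filtered already.
#'
#' @param exome_snv Data frame of exome SNV hits with columns `gene`,
#'   `family`, `variant_id` (may be `NULL`).
#' @param exome_cnv Data frame of exome CNV gene hits with columns
#'   `gene`, `family` (may be `NULL`).
#' @param public_cnv_genes,public_snp_genes Character vectors of gene
#'   symbols from public CNV studies and GWAS SNP annotations.
#' @return Data frame of class `evidence_matrix`: `gene`, logical
#'   `public_cnv`, `public_snp`, `exome_cnv`, `exome_snv`, `sv2c`,
#'   `two_vsc`, and `n_families` (families contributing exome evidence).
#' @export
build_evidence_matrix <- function(exome_snv = NULL, exome_cnv = NULL,
                                  public_cnv_genes = character(),
                                  public_snp_genes = character()) {
  if (!is.null(exome_snv)) {
    assert_columns(exome_snv, c("gene", "family", "variant_id"), "exome_snv")
  }
  if (!is.null(exome_cnv)) {
    assert_columns(exome_cnv, c("gene", "family"), "exome_cnv")
  }
  genes <- sort(unique(c(
    if (!is.null(exome_snv)) exome_snv$gene,
    if (!is.null(exome_cnv)) exome_cnv$gene,
    public_cnv_genes, public_snp_genes)))
  if (length(genes) == 0L) {
    out <- data.frame(gene = character(), public_cnv = logical(),
                      public_snp = logical(), exome_cnv = logical(),
                      exome_snv = logical(), sv2c = logical(),
                      two_vsc = logical(), n_families = integer())
    class(out) <- c("evidence_matrix", class(out))
    return(out)
  }
  per_gene <- function(g) {
    snv <- if (is.null(exome_snv)) NULL else
      exome_snv[exome_snv$gene == g, , drop = FALSE]
    cnv <- if (is.null(exome_cnv)) NULL else
      exome_cnv[exome_cnv$gene == g, , drop = FALSE]
    sv2c <- FALSE
    two_vsc <- FALSE
    if (!is.null(snv) && nrow(snv) > 0L) {
      fam_per_variant <- tapply(snv$family, snv$variant_id,
                                function(f) length(unique(f)))
      sv2c <- any(fam_per_variant >= 2L)
      vars_per_family <- tapply(snv$variant_id, snv$family,
                                function(v) length(unique(v)))
      two_vsc <- any(vars_per_family >= 2L)
    }
    if (!is.null(cnv) && nrow(cnv) > 0L &&
        length(unique(cnv$family)) >= 2L) {
      sv2c <- TRUE
    }
    fams <- unique(c(if (!is.null(snv)) snv$family,
                     if (!is.null(cnv)) cnv$family))
    data.frame(gene = g,
               public_cnv = g %in% public_cnv_genes,
               public_snp = g %in% public_snp_genes,
               exome_cnv = !is.null(cnv) && nrow(cnv) > 0L,
               exome_snv = !is.null(snv) && nrow(snv) > 0L,
               sv2c = sv2c, two_vsc = two_vsc,
               n_families = length(fams), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(genes, per_gene))
  rownames(out) <- NULL
  class(out) <- c("evidence_matrix", class(out))
  out
}

#' Select seed genes by the two-evidence rule
#'
#' A gene qualifies as a seed when it carries at least two independent
#' pieces of evidence: flagged in at least two distinct evidence
#' categories, or recurrent within one category across families
#' (`sv2c`), or hit by two variants in the same child (`two_vsc`).
#'
#' @param matrix An evidence matrix (from [build_evidence_matrix()] or
#'   [as_evidence_matrix()]) with logical columns `public_cnv`,
#'   `public_snp`, `exome_cnv`, `exome_snv`, `sv2c`, `two_vsc`.
#' @return Character vector of selected gene symbols.
#' @export
select_seeds <- function(matrix) {
  assert_columns(matrix, c("gene", "public_cnv", "public_snp", "exome_cnv",
                           "exome_snv", "sv2c", "two_vsc"), "matrix")
  n_cat <- rowSums(matrix[, c("public_cnv", "public_snp",
                              "exome_cnv", "exome_snv")])
  matrix$gene[n_cat >= 2L | matrix$sv2c | matrix$two_vsc]
}

#' Per-child variant profile summary
#'
#' Labels each child by the origin of its candidate variants
#' (`inherited_only`, `de_novo_SNV`, `de_novo_CNV`, or `both`), and, when
#' comorbidity counts are provided, reports the mean comorbidity count of
#' the inherited-only group, of the any-de-novo group, and their ratio.
#'
#' @param children Data frame with one row per child: `child`,
#'   `n_de_novo_snv`, `n_de_novo_cnv`, optionally `n_inherited` and
#'   `n_comorbidities`.
#' @return List with `profiles` (the input plus a `profile` column),
#'   `group_sizes` (named integer vector over the four labels), and
#'   `comorbidity` (`NULL` unless counts were provided: means per group
#'   and the inherited/de novo ratio).
#' @export
profile_summary <- function(children) {
  assert_columns(children, c("child", "n_de_novo_snv", "n_de_novo_cnv"),
                 "children")
  snv <- children$n_de_novo_snv > 0L
  cnv <- children$n_de_novo_cnv > 0L
  profile <- ifelse(snv & cnv, "both",
                    ifelse(snv, "de_novo_SNV",
                           ifelse(cnv, "de_novo_CNV", "inherited_only")))
  children$profile <- profile
  labels <- c("inherited_only", "de_novo_SNV", "de_novo_CNV", "both")
  sizes <- setNames(vapply(labels, function(l) sum(profile == l),
                           integer(1)), labels)
  comorbidity <- NULL
  if ("n_comorbidities" %in% names(children)) {
    inh <- children$n_comorbidities[profile == "inherited_only"]
    dnv <- children$n_comorbidities[profile != "inherited_only"]
    comorbidity <- list(
      mean_inherited_only = if (length(inh)) mean(inh) else NA_real_,
      mean_de_novo = if (length(dnv)) mean(dnv) else NA_real_,
      ratio = if (length(inh) && length(dnv) && mean(dnv) > 0) {
        mean(inh) / mean(dnv)
      } else NA_real_)
  }
  list(profiles = children, group_sizes = sizes, comorbidity = comorbidity)
}
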