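make_gene_models <- function(n = 20, chrom = "chr1", width = 5000L,
                             gap = 5000L) {
  start <- seq(1L, by = width + gap, length.out = n)
  data.frame(symbol = sprintf("G%02d", seq_len(n)), chrom = chrom,
             start = start, end = start + width - 1L,
             stringsAsFactors = FALSE)
}

test_that("region-to-gene mapping equals a brute-force scan", {
  genes <- make_gene_models()
  region <- list(chrom = "chr1", start = genes$start[2] - 100,
                 end = genes$start[3] + 10)
  expect_setequal(genes_in_region(region, genes),
                  c("G02", "G03"))
  between <- list(chrom = "chr1", start = genes$end[1] + 1,
                  end = genes$start[2] - 1)
  expect_length(genes_in_region(between, genes), 0)
  set.seed(31)
  for (i in 1:50) {
    r <- list(chrom = sample(c("chr1", "chr2"), 1),
              start = sample.int(2e5, 1))
    r$end <- r$start + sample.int(3e4, 1)
    brute <- genes$symbol[genes$chrom == r$chrom &
                            genes$start <= r$end & genes$end >= r$start]
    expect_setequal(genes_in_region(r, genes), brute)
  }
  # union-distribution over region lists
  r1 <- list(chrom = "chr1", start = 1, end = 20000)
  r2 <- list(chrom = "chr1", start = 50000, end = 90000)
  expect_setequal(union(genes_in_region(r1, genes),
                        genes_in_region(r2, genes)),
                  unique(c(genes_in_region(r1, genes),
                           genes_in_region(r2, genes))))
})

test_that("brain-expression filter is inclusive at the RPKM threshold", {
  expr <- data.frame(gene = c("A", "B", "C"), max_rpkm = c(1.0, 0.2, 7))
  kept <- brain_filter(c("A", "B", "C", "D"), expr)
  expect_setequal(as.character(kept), c("A", "C"))
  expect_identical(attr(kept, "missing"), "D")
  expect_error(brain_filter("A", data.frame(gene = "A", max_rpkm = -1)),
               "non-negative")
})

test_that("olfactory receptor removal reproduces an 1128 - 80 gene set", {
  expect_identical(remove_olfactory(c("OR8K3", "CYFIP2")), "CYFIP2")
  plain <- c("CYFIP2", "NPSR1", "OBSL1")
  expect_identical(remove_olfactory(plain), plain)
  or_genes <- sprintf("OR%d%s%d", sample(1:52, 80, replace = TRUE),
                      sample(LETTERS, 80, replace = TRUE),
                      sample(1:9, 80, replace = TRUE))
  others <- sprintf("GENE%04d", seq_len(1048))
  full <- sample(c(or_genes, others))
  expect_length(full, 1128)
  expect_setequal(remove_olfactory(full), others)
  expect_length(remove_olfactory(full), 1048)
})

test_that("evidence matrix flags categories and recurrence annotations", {
  snv <- data.frame(
    gene = c("A", "A", "B", "B", "C"),
    family = c("f1", "f2", "f3", "f3", "f4"),
    variant_id = c("v1", "v1", "v2", "v3", "v4"),
    stringsAsFactors = FALSE)
  cnv <- data.frame(gene = c("C", "D", "D"), family = c("f4", "f1", "f5"),
                    stringsAsFactors = FALSE)
  m <- build_evidence_matrix(snv, cnv, public_cnv_genes = c("C", "E"),
                             public_snp_genes = "E")
  expect_setequal(m$gene, c("A", "B", "C", "D", "E"))
  a <- m[m$gene == "A", ]
  expect_true(a$sv2c)          # v1 in two families
  expect_false(a$two_vsc)
  b <- m[m$gene == "B", ]
  expect_true(b$two_vsc)       # v2 and v3 in f3
  expect_false(b$sv2c)
  cc <- m[m$gene == "C", ]
  expect_true(cc$exome_snv && cc$exome_cnv && cc$public_cnv)
  d <- m[m$gene == "D", ]
  expect_true(d$sv2c)          # CNV gene hit in two families
  expect_identical(nrow(build_evidence_matrix()), 0L)
})

test_that("seed selection equals the row-wise two-evidence predicate and is monotone", {
  set.seed(13)
  for (i in 1:20) {
    n <- 30
    m <- data.frame(gene = sprintf("g%02d", 1:n),
                    public_cnv = sample(c(TRUE, FALSE), n, TRUE),
                    public_snp = sample(c(TRUE, FALSE), n, TRUE, c(0.2, 0.8)),
                    exome_cnv = sample(c(TRUE, FALSE), n, TRUE),
                    exome_snv = sample(c(TRUE, FALSE), n, TRUE),
                    sv2c = sample(c(TRUE, FALSE), n, TRUE, c(0.2, 0.8)),
                    two_vsc = sample(c(TRUE, FALSE), n, TRUE, c(0.2, 0.8)),
                    stringsAsFactors = FALSE)
    brute <- m$gene[vapply(seq_len(n), function(j) {
      sum(c(m$public_cnv[j], m$public_snp[j], m$exome_cnv[j],
            m$exome_snv[j])) >= 2 || m$sv2c[j] || m$two_vsc[j]
    }, logical(1))]
    expect_identical(select_seeds(m), brute)
    # monotone: adding evidence never removes a seed
    m2 <- m
    flip <- sample.int(n, 5)
    m2$public_snp[flip] <- TRUE
    expect_true(all(select_seeds(m) %in% select_seeds(m2)))
  }
})

test_that("per-child profiles label variant origin and comorbidity ratio", {
  children <- data.frame(
    child = c("c1", "c2", "c3", "c4"),
    n_de_novo_snv = c(1L, 0L, 0L, 2L),
    n_de_novo_cnv = c(0L, 1L, 0L, 1L),
    n_inherited = c(3L, 2L, 5L, 1L),
    n_comorbidities = c(1, 1, 4, 2))
  ps <- profile_summary(children)
  expect_identical(ps$profiles$profile,
                   c("de_novo_SNV", "de_novo_CNV", "inherited_only", "both"))
  expect_identical(unname(ps$group_sizes["inherited_only"]), 1L)
  expect_equal(ps$comorbidity$mean_inherited_only, 4)
  expect_equal(ps$comorbidity$mean_de_novo, mean(c(1, 1, 2)))
  expect_equal(ps$comorbidity$ratio, 4 / mean(c(1, 1, 2)))
  # a cohort where no child has both kinds
  no_both <- children[1:3, ]
  expect_identical(unname(profile_summary(no_both)$group_sizes["both"]), 0L)
})
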