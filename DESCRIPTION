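Package: trionet
Title: Trio Exome Variant Triage, CNV False-Positive Screening, and
    Network-Based Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for integrative analysis of parent-child trio exome data
    in neurodevelopmental disorders. Implements robust moment-based kinship
    estimation for trio quality control, three-rule triage of annotated
    single-nucleotide variants (de novo moderate/high impact, rare recessive,
    and very rare high-impact heterozygous), a false-positive screen for
    exome copy-number variant calls based on internal SNV allele evidence
    (heterozygosity rate for deletions, B-allele frequency for duplications)
    with inheritance classification, integration of exome and public evidence
    into a gene-by-category matrix with a two-evidence seed rule,
    protein-protein interaction network expansion with broker and bottleneck
    topology measures, and hypergeometric over-representation analysis.
    Includes a synthetic-data generator that emulates every input with known
    ground truth so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
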