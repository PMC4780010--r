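---
title: "Methods: trio variant triage, CNV screening and network integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio variant triage, CNV screening and network integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trionet)
```

## Scope and model

trionet implements an integrative analysis for parent-child trio exome
studies of neurodevelopmental disorders such as ADHD. The pipeline
assumes upstream processing (alignment, genotype calling, consequence
and population-frequency annotation, exome CNV segmentation) has already
happened; its inputs are annotated per-family variant tables, XHMM-style
CNV call tables with per-site allele read counts, control CNV intervals,
a brain-expression table, public evidence gene lists, and a
protein-protein interaction edge list with per-edge experimental
evidence counts. Every input can be emulated, with known ground truth,
by the synthetic-data generators, so the full pipeline is testable
without any download.

## Trio quality control by kinship

Within a trio, relatedness is estimated with the robust within-family
moment estimator

$$\hat\phi = \frac{N_{Aa,Aa} - 2\,N_{AA,aa}}{N_{Aa,i} + N_{Aa,j}},$$

counting double-heterozygous sites, opposite-homozygous sites and the
per-sample heterozygote totals over sites genotyped in both samples.
We use the within-family (homogeneous population) form because every
comparison is parent versus child inside one family; its anchors are
exact: duplicates give $\hat\phi = 0.5$, parent-offspring concentrates
near 0.25, unrelated pairs near 0. Sites with a missing genotype in
either sample are dropped pairwise. In exome data a genuine parent-child
pair is expected to land between 0.17 and 0.35.

Two exclusion conventions circulate for the lower cutoff (0.17 with
boundary trios also removed, or 0.19); rather than hard-coding one,
`qc_trios()` exposes `exclusion_threshold` (default 0.17) and a
`strict_boundary` flag under which a kinship exactly at the threshold
also fails. Both conventions are therefore reachable from configuration.

## Three-rule SNV triage

Frequency classes follow the usual exome bands on the maximum population
minor allele frequency: *common* above 5%, *rare* in the closed interval
[1%, 5%], *very rare* below 1%, *novel* when absent from the databases.
The prose conventions "greater than 5%" and "less than 1%" are strict,
so both interior boundaries fall into *rare*; this choice is documented
here and fixed, not configurable per call site. Impact maps nonsense and
splice-site variants to HIGH, missense to MODERATE, everything else to
`other`.

The three candidate rules are:

1. **De novo, moderate/high impact** - child carries the alternate
   allele, both parents homozygous reference. No frequency filter is
   applied: genuinely de novo events can carry any population
   frequency, and published de novo candidate lists include common
   alleles.
2. **Rare recessive** - child homozygous alternate, both parents
   heterozygous, missense, frequency class strictly *rare* (novel
   variants are not admitted; the rule is about observed rare alleles).
3. **Very rare, high impact, heterozygous** - child heterozygous,
   nonsense or splice site, class *very rare* or *novel*, and the allele
   present in exactly one heterozygous parent. Requiring one carrier
   parent makes rules 1 and 3 disjoint by construction: no site can be
   counted both as de novo and as inherited.

All rules require read depth of at least 10 in *all three* members (the
conservative reading of a trio depth filter - an undercovered parent
cannot support a de novo claim) and restrict to brain-expressed genes.
Records with a missing genotype are skipped and counted, never silently
dropped.

Recurrence is summarized per gene (same variant in two or more families,
`sv2c`; two or more variants of one gene in one child, `two_vsc`) and
per *major* cytogenetic band, obtained by stripping the sub-band suffix
(`19p13.2` to `19p13`), which is how band-level clustering across
families is conventionally reported.

## CNV false-positive screening

Exome CNV callers segment noisy depth-of-coverage signal, so the
pipeline layers independent screens over the raw calls:

* **quality**: at least 3 targeted exons, at least 1 kb, both
  phred-scaled qualities (some event; not diploid) at least 90 - all
  inclusive bounds, matching the prepositions "at least";
* **controls**: any overlap with a population-control CNV removes the
  call;
* **parent frequency**: a call carried by *more than* three distinct
  healthy parents (strictly greater) is a likely systematic artifact;
* **allele evidence**: inside a true hemizygous deletion no site can be
  heterozygous, so a heterozygous-SNV rate strictly above 10% flags a
  false positive (rate undefined without sites - such calls are
  retained and flagged, because absence of evidence is not failure);
  inside a true duplication heterozygous sites show B-allele
  frequencies near 1/3 or 2/3, so a mean BAF strictly inside (0.4, 0.6)
  flags a false positive.

The raw-mean duplication screen has a known blind spot: a true
duplication whose het sites split evenly between 1/3 and 2/3 averages
to 0.5 and is removed. We implement the raw mean because that is the
screen as described, and additionally expose `folded_baf = TRUE`, which
averages $|BAF - 0.5|$ and separates split BAFs from genuinely diploid
signal; the choice is a flag, not a guess.

The control, parent-frequency and evidence screens are independent
predicates of each call, so the retained set does not depend on the
order in which they are applied; `run_cnv_pipeline()` computes all of
them and emits a per-call audit table with every decision. Inheritance
is classified afterwards against the child's own parents (overlapping
same-type call in father only, mother only, both, or neither), on the
view that a call's parent-of-origin is a property of the retained call,
not a filter; the overlap criterion everywhere is any-overlap
(`min_fraction = 0`) by default with a configurable fraction, since no
reciprocal-overlap fraction is standard for this matching. Coordinates
are 1-based closed in memory; BED input is converted at the boundary.

## Evidence integration and the two-evidence seed rule

Variant and CNV hits are mapped to genes, restricted to brain-expressed
genes (maximum RPKM across areas and samples at least 1 - "1 RPKM"
read inclusively), and olfactory receptors are removed by symbol
pattern (`OR` + digit) or explicit flag to avoid their familiar
enrichment bias. The evidence matrix holds one row per gene with four
category flags (exome SNV, exome CNV, public SNP, public CNV) and the
recurrence annotations. A gene becomes a **seed** when it has at least
two evidences: two distinct categories, or recurrence across families
within one category (`sv2c`), or two variants in the same child
(`two_vsc`). The recurrence clauses are part of the rule because
within-analysis recurrence is accepted as a second evidence in the
tabulated convention this rule reproduces; a stricter
"two different analyses" reading would drop single-category recurrent
genes, and the packaged 30-gene table shows that is not the intended
behaviour. The rule is monotone: adding evidence can only add seeds.

## Network topology

The interactome keeps only edges supported by at least two pieces of
direct experimental evidence (duplicate records merged by summing
counts, self-loops dropped) and is treated as a simple undirected
graph. Seeds are expanded by their direct neighbors (optionally
restricted to a whitelist such as brain-expressed genes), and per-node
topology is computed:

* local clustering coefficient $C(v) = 2T(v)/(d(v)(d(v)-1))$, defined
  as 0 when $d(v) < 2$;
* betweenness centrality, unweighted shortest-path (Brandes), endpoints
  excluded, each unordered pair once, normalized by
  $2/((n-1)(n-2))$ - stated explicitly because only the induced ranking
  matters for classification;
* brokering centrality $(d(v)/d_{\max})(1 - C(v))$, which is maximal
  for a star hub and zero inside a clique. The literature on brokering
  describes the concept (hubs whose neighbors do not connect) without a
  unique printed formula; this normalized-degree form satisfies every
  stated property and is isolated in one function so an alternative can
  be swapped in.

The top 5% (by ceiling, ties broken lexicographically by node name for
determinism) of brokering and betweenness are classified as brokers and
bottlenecks respectively, and the seed-centrality report measures what
fraction of seed genes is central - in disease networks seeds are
typically peripheral.

## Over-representation analysis

Enrichment of a study gene set in user-supplied categories uses the
exact upper-tail hypergeometric probability $P[X \ge k]$ (via
`phyper`, stable in the far tail), adjusted across categories by
Benjamini-Hochberg or Bonferroni, with the reporting rule: at most the
top 10 terms with adjusted p below 0.05. Only over-representation is
tested; the universe defaults to the full annotation set and can be
restricted (e.g. to brain-expressed genes). Category databases are
consumed as plain term-to-gene tables; no live annotation service is
queried.

## The synthetic-data generators

`generate_trio_cohort()` draws parental genotypes under Hardy-Weinberg
at per-site allele frequencies uniform on `maf_range` (default
0.05-0.5) and builds the child by sampling one allele from each parent,
so every non-planted site is Mendelian consistent and, under the
default frequency range, classified *common* - which guarantees that
only planted sites can satisfy the triage rules and makes truth
recovery exact rather than probabilistic. Planted events implement the
exact genotype/annotation patterns of the three rules; decoys realize
near-miss de novo candidates violating exactly one criterion (a parent
depth of 9, a synonymous consequence, or a non-brain gene). Depth is
Poisson (mean 40, the coverage scale of a typical exome) truncated at 1.

`generate_cnv_calls()` tiles one synthetic chromosome per family with
fixed-width exons (150 bp every 1 kb) and gives each call site-level
allele evidence under a binomial read model. True duplications are
simulated with all heterozygous B alleles in phase on the duplicated
haplotype, so their mean BAF concentrates at 1/3 or 2/3; this is the
regime the raw-mean screen is designed for, and it deliberately avoids
the screen's symmetric blind spot, which is exercised separately with
constructed cases. Artifact deletions draw their het fraction from
0.15-0.40, comfortably above the 10% cutoff relative to binomial noise
at the default site counts (about one evidence site per 300 bp).

`generate_ppi()` grows a preferential-attachment graph
(`igraph::sample_pa`), giving the heavy-tailed degree distribution of
curated interactomes at reduced scale, with per-edge evidence counts
1 + Poisson(1.5) by default.

What the generators do **not** emulate: linkage disequilibrium,
population structure, genotyping error, GC-dependent coverage, breakpoint
uncertainty in CNV calls, or the literature bias of interactome
curation. Passing tests therefore demonstrate correctness of the
decision logic under the stated evidence model, not performance on real
cohorts.

A packaged deterministic cohort, `synthetic_cnv_cohort()`, combines 13
true events (3 de novo, 7 paternal, 3 maternal) with one artifact per
removal mechanism; it is entirely simulated and serves as a
composition-realistic end-to-end fixture for the CNV pipeline.

## Numerical and engineering choices

* Genotypes are categorical (`hom_ref`/`het`/`hom_alt`/`missing`);
  multi-allelic sites are out of scope, keeping all predicates
  single-alternate.
* All interval arithmetic is 1-based closed in memory; BED files
  (0-based half-open) are converted on read via rtracklayer.
* Kinship with no heterozygous site in either sample is an error naming
  the pair, not a silent `NaN`.
* Frequency and quality boundaries follow the preposition of their
  definitions: "greater than"/"less than"/"above" strict, "at least"
  and "between 1% and 5%" inclusive, "between 0.4 and 0.6" exclusive.
* Tie-breaks in top-fraction classification are lexicographic, and ORA
  output is sorted by adjusted p, raw p, then term id, so results never
  depend on input iteration order.
* Problem sizes in the test-suite: triage oracles run on cohorts of at
  most 1,000 sites, graph-metric oracles on 100 random graphs of at
  most 30 nodes, kinship simulations on 50,000 sites over 10 seeds, and
  the CNV screen-recovery property over 20 simulator seeds - sizes at
  which the brute-force oracles are exact and fast.

## Known limitations

Compound-heterozygote phasing, X-linked models, indels and structural
variants other than CNVs, LD-based SNP-to-gene assignment, liftover
between assemblies, and the upstream callers themselves are all out of
scope. The duplication BAF screen inherits the symmetric-mean caveat
described above. The brokering formula is one defensible realization of
the published concept, not a transcription of a printed equation.

## A worked micro-example

```{r example}
cfg <- sim_config(n_trios = 2, n_sites = 400, n_true_denovo_per_trio = 2,
                  n_decoy_per_trio = 3, rng_seed = 7)
cohort <- generate_trio_cohort(cfg)
qc_trios(cohort)
res <- triage(cohort$variants, cohort$brain_genes)
res
subset(cohort$truth, event == "de_novo")
```
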