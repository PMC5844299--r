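---
title: "Analysing sparse insect CpG methylomes with sparsemeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing sparse insect CpG methylomes with sparsemeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsemeth)
```

## The problem

Insect genomes are sparsely methylated: typically well under 1% of CpG
cytosines carry 5-methyl-cytosine, methylation is concentrated in the
exons of a distinct subset of "gene-body methylated" genes, and the rest
of the genome is essentially unmethylated. Whole-genome bisulfite
sequencing (WGBS) reads this signal out as counts: unmethylated
cytosines are converted to uracil (sequenced as T), methylated
cytosines are protected (sequenced as C), so at each cytosine the pair
(methylated reads, unmethylated reads) carries the methylation signal,
contaminated by a small bisulfite *non-conversion* error — the roughly
1% of unmethylated cytosines that fail to convert and masquerade as
methylated.

`sparsemeth` implements the downstream analysis stack for this setting:

1. **Per-site calling** (`call_sites`): a one-sided binomial test of
   `n_meth` out of `n_total` reads against the null that every
   methylated read is a conversion failure, with Benjamini–Hochberg
   control across sites.
2. **Feature summaries** (`assign_sites`, `compute_ratios`,
   `classify_genes`): methylation ratios mCpG/CpG over exons, introns
   and 2 kb upstream windows, and the two-class gene partition at the
   "ratio > 10%" rule.
3. **CpG depletion** (`compute_cpg_oe`, `gene_cpg_oe`,
   `compare_oe_classes`): the observed/expected CpG statistic
   `(n_CG * L) / (n_C * n_G)`, which records *historical* methylation
   through deamination of methyl-cytosine to thymine.
4. **Modality testing** (`dip_statistic`, `dip_test`): Hartigan's dip,
   implemented from scratch (see below), to test bimodality of
   methylation-ratio and CpG O/E distributions.
5. **Expression integration** (`join_expression` and friends):
   Spearman correlation of gene-body methylation with TMM-normalised
   FPKM, class-wise rank comparisons, silent-gene overlap, binned
   profiles.
6. **Enrichment** (`fisher_enrichment`): one-sided Fisher tests of
   term annotation in a target set against a background, BH-adjusted.
7. **Targeted amplicons** (`amplicon_site_fractions`,
   `amplicon_compare_groups`, `concordance_wgbs`): per-site fractional
   methylation across individual samples, two-phenotype Student t
   comparisons, and validation against the WGBS track.
8. **A synthetic-data generator** (`sim_config`, `simulate_genome`,
   `simulate_counts`, `simulate_expression`,
   `simulate_amplicon_panel`) that produces genomes, annotations,
   count tables, expression tables and amplicon panels with the
   statistical structure the analysis assumes, so the whole pipeline is
   testable end to end without sequencing data.

## The calling model

At a site with `n` reads, `k` of which report methylation, the null is
`k ~ Binomial(n, e)` with `e` the non-conversion error rate, and the
p-value is the upper tail `P[X >= k]`. The test is one-sided by
construction: under the error-rate null there is no meaningful
"less methylated than error" alternative. `e` is best estimated from
the data itself (`estimate_error_rate`): insect methylation is
essentially CpG-only, so pooled CHG/CHH counts measure pure
non-conversion. The default `e = 0.01` corresponds to the > 99%
conversion typical of current kits.

Sites with fewer than `min_reads` total reads (default 2; 10 as the
strict variant) are excluded *before* testing, so the BH family is the
set of tested sites; excluding them afterwards would leave the family
polluted with untestable sites. A site is called methylated at adjusted
p < 0.05.

Two modelling notes. First, the per-cytosine report keeps the two
strands of a symmetric CpG as separate sites; the package follows that
granularity rather than merging strands, matching the input's
resolution. Second, the caller's null is exact when the true
methylation fraction is zero; weakly methylated sites are genuine
(if small) alternatives, which matters when interpreting the
false-discovery proportion on simulated data.

## Ratios, classes, and why the generator is zero-inflated

The methylation ratio of a feature is the number of *called* CpG sites
over the number of *detected* CpG sites — a detection-calibrated
quantity, not an estimate of mean per-site methylation. Genes with no
detected exonic CpGs get an undefined (`NA`) ratio and are excluded
from classification, with their count reported.

The generator models the two gene classes with per-site true
methylation fractions drawn from Beta distributions: `Beta(8, 2)` for
exonic sites of highly methylated genes, `Beta(0.5, 20)` for the low
class, with intergenic background at 0.002. Two refinements matter:

* **Exon bias.** Within methylated genes only exonic sites draw from
  the high Beta; intronic sites draw from the low model. This mirrors
  the strong exon concentration of insect gene-body methylation and
  makes the exon-vs-intron ratio ordering an emergent property.
* **Zero inflation of the low class.** Only a fraction
  (`frac_low_sites_methylated`, default 0.08) of low-class sites carry
  any methylation; the rest are exactly zero. A pure `Beta(0.5, 20)`
  low class puts a few percent methylation at *every* site, which has
  two unrealistic consequences: no gene is ever free of methylated
  calls (real sparse methylomes have ~40% of genes with zero methylated
  CpGs), and as coverage grows the binomial test detects ever more of
  the weak sites, pushing the low class's called-site ratio through the
  10% classification cutoff. With zero inflation at 0.08 the low
  class's asymptotic mCpG/CpG ratio stays below the cutoff at any
  depth, which is the internal-consistency condition for the "> 10%"
  rule to define classes at all. The value 0.08 is a modelling choice
  pinned by that condition (it must be clearly below 0.10) and by the
  observed share of methylation-free genes.

Coverage is negative binomial around 28x (the depth scale of a typical
WGBS study; `nb_size = 5` gives realistic overdispersion). Counts are
`Binomial(coverage, m + (1 - m) e)`: non-conversion can only inflate
the methylated count; inappropriate conversion of methylated cytosines
is taken as absent.

CpG depletion is implemented at the *sequence* level: in highly
methylated genes each CG dinucleotide is replaced by TG or CA with
probability `deamination_strength` (default 0.2) when the genome is
constructed. CpG O/E is then computed from the final sequence, so the
negative correlation between methylation and CpG O/E is emergent, not
painted on.

Expression is log-normal around `baseline_log_expr` (0.7, i.e. ~5
FPKM) with an additive log10 offset (`expression_coupling`, 0.8) for
the methylated class and a silenced fraction (FPKM = 0) drawn from the
nonmethylated class — together these reproduce the positive, nonlinear
methylation-expression relationship and the excess of methylation-free
genes among silent genes.

What the generator does *not* emulate: read-level artefacts (mapping
bias, PCR duplicates), sequence composition beyond a single GC
fraction, correlated methylation along the genome (sites are
independent given class), and annotation error. Passing tests therefore
demonstrate the statistical machinery under the stated model, not
robustness to those real-data complications.

## The dip statistic

Hartigan's dip — the sup-norm distance between the empirical CDF and
the closest unimodal CDF — is implemented from first principles in
C++. The computation reduces the sample to distinct values with
cumulative counts, and asks, for a candidate fit distance, whether some
mode placement admits a CDF that is convex left of the mode and concave
right of it inside the sup-norm band:

* band feasibility of the convex side is a greatest-convex-minorant
  condition (the hull of the upper band edges must clear the lower
  edges), and mirrored for the concave side;
* the two sides must *link*: the smallest value the convex side can
  reach at the mode (convex extrapolation forces it up) must not exceed
  the largest value the concave side can start from. These extremes are
  computed exactly by a dynamic programme whose state is the convex
  polygon of achievable (final slope, value) pairs — a scalar profile
  is insufficient, because a chain that runs higher early can afford a
  flatter extrapolation later.

The dip is the smallest feasible distance, found by bisection; each
probe costs one forward and one backward sweep. Exactness was checked
against an independent linear-programming oracle (exhaustive over mode
placements) on hundreds of small samples, and the closed forms are
exact: an equispaced sample of size n gives 1/(2n), a balanced
two-point mixture gives 0.25. The `dip_test` p-value is Monte Carlo
against uniform samples of the same size (the standard reference null),
seeded, with the plus-one correction; `n_boot = 2000` puts the
resolution of small p-values at ~5e-4.

## Statistical choices worth knowing about

* **BH adjustment** is written as the explicit step-up rule and
  cross-checked against `stats::p.adjust` in the tests; the package
  exposes it because the calling family (tested sites only) is a
  modelling decision, not a mechanical default.
* **Enrichment** uses one-sided Fisher tests (enrichment direction), as
  is standard for term enrichment; two-sided would mix depletion into
  the ranking.
* **Class comparisons of expression** default to the two-independent-
  sample rank-sum test: the methylated and nonmethylated gene sets are
  disjoint, so a signed-rank (paired) design has no natural pairing. A
  signed-rank variant on sorted-value pairing is provided for
  completeness but is descriptive only.
* **CpG O/E class comparison** reports both a variance-ratio F (with
  class-size degrees of freedom) and a Welch mean comparison; which
  moment comparison is "the" test is left to the reader, and neither is
  privileged.
* **Amplicon comparisons** use the equal-variance Student t-test by
  default (Welch by flag), report raw p-values per site — a targeted
  panel of a handful of candidate loci is conventionally read
  unadjusted — and emit a BH column alongside. Group means average
  per-sample fractions (each moth is the experimental unit), rather
  than pooling reads across samples. The difference is long-distance
  minus short-distance.
* **Degenerate inputs**: sites with identical group values give p = 1
  rather than a t-test failure; genes with undefined ratios are
  excluded and counted; empty bins are retained with n = 0; zero-FPKM
  genes are excluded from log-scale summaries but kept in rank
  statistics.

## Problem sizes in the test-suite and acceptance runs

The shipped checks run the generator at desk scale, chosen to keep each
property measurable with comfortable statistical margin: the
false-discovery check on a ~200,000-CpG genome (2.4 Mb, 400 genes); the
class-recovery check at 2,000 genes and 60x depth; emergent-structure
checks at the default 400 genes and 28x; amplicon null calibration over
500 replicate 10-site panels of 8 vs 8 samples at 500x. These sizes are
the package's own choices for stable yet quick verification; the model
itself has no scale assumptions beyond them.

## A worked run

```{r pipeline, eval = FALSE}
library(sparsemeth)

sim <- simulate_genome(sim_config(seed = 1))
report <- simulate_counts(sim)                  # full cytosine report

err <- estimate_error_rate(report)              # from CHG/CHH sites
calls <- call_sites(report, error_rate = err, min_reads = 2)
summarize_calls(calls, genome_cpg_total = nrow(enumerate_genome_cpgs(sim$genome)))

ratios <- compute_ratios(assign_sites(calls, sim$models), calls)
classes <- classify_genes(ratios, threshold = 0.10)

dip_test(classes$exon_ratio, n_boot = 2000, seed = 1)

oe <- gene_cpg_oe(sim$genome, sim$models)
compare_oe_classes(oe, classes)

genes <- merge(ratios$genes, classes[, c("gene_id", "class")],
               by = "gene_id")
joined <- join_expression(genes, simulate_expression(sim))
correlate_methylation_expression(joined)
```

## Known limitations

* The caller tests each site independently; no smoothing or spatial
  borrowing is done (appropriate at sparse methylation levels, where
  neighbouring-site correlation is weak outside methylated genes).
* The binomial null treats the error rate as known; its estimation
  uncertainty (tiny when pooled over millions of non-CpG sites) is
  ignored.
* The 10% classification cutoff is coverage-calibrated by its nature:
  the ratio counts *detected* methylation, so its meaning shifts with
  depth. The generator's zero-inflated low class keeps the rule
  consistent across depths, but on real data from a very different
  depth the cutoff deserves a fresh look.
* A single pooled WGBS sample is assumed; differential methylation
  between WGBS samples is out of scope (the amplicon module handles the
  two-group design).
* `read_gff` resolves one level of exon-to-gene indirection
  (exon -> mRNA -> gene); deeper feature hierarchies are not handled.
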