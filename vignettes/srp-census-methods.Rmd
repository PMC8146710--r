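---
title: "Methods: censusing prophages and CRISPR arrays in sulfate-reducing prokaryotes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: censusing prophages and CRISPR arrays in sulfate-reducing prokaryotes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srpcensus)
```

Sulfate-reducing prokaryotes (SRP) are anaerobes that respire sulfate to
sulfide and anchor the sulfur and carbon cycles of anoxic sediments,
wetlands and engineered reactors. Two genomic records of their interactions
with viruses are integrated prophages (temperate phage genomes resident in
the host chromosome) and CRISPR arrays (spacer libraries recording past
invaders). `srpcensus` implements a desk pipeline for censusing both
elements across a panel of SRP genomes and relating carriage to host
ecophysiology — cell geometry, growth rate, habitat, pH/temperature optima,
GC content and genome size. This vignette is the package's account of the
methods: the models, the tunable parameters and their defaults, the
numerical conventions, and what the synthetic-data generator does and does
not establish.

## Consensus prophage calling

Prophage prediction tools disagree, and each has characteristic false
positives. The pipeline therefore consumes interval sets from **two
independent detectors** and keeps only regions where both agree. For every
pair of overlapping A/B intervals (overlap of at least `min_overlap` bp,
default 1, with no reciprocal-fraction requirement) the pairwise
**intersection** is emitted by default; overlapping or book-ended emitted
regions on the same replicon are then merged into one call. The
intersection is the conservative coordinate choice: consensus boundaries
are an artefact of two detectors' windowing, so the region both agree on is
the defensible core. The pairwise **union** span is available via
`mode = "union"` for sensitivity analyses; every intersection-mode call is
contained in the corresponding union-mode call.

All internal coordinates are 0-based half-open (BED convention); lengths
are `end - start`. GFF3 and the legacy 1-based-inclusive TSV dialect are
converted on input. Calls are numbered `<strainIndex>R<serial>` by start
coordinate within each strain.

Calls shorter than 30 kb (strict inequality) are classed **small**; such
elements are enriched in remnants and satellite elements since intact
tailed-phage genomes rarely fit below that size. Per-strain burden is
reported both as total prophage bp and as a percent of the genome (two
decimals, half-up). Prevalence percentages are rounded **half away from
zero**; this is the convention that reproduces each printed percentage of
the worked example (56, 78, 68, 43, 15, 5).

Replicons are analysed separately by default. Where an upstream tool
required short plasmids to be concatenated to the chromosome,
`concatenate_replicons()` reproduces that layout and returns the junction
positions so junction-spanning calls can be rejected — a compatibility
mode, not the recommended path.

## CRISPR census

CRISPR detectors grade each candidate array with an evidence level 1-4;
level 1 is dominated by spurious repeat structures. `filter_arrays()` keeps
levels 2-4 (configurable), and the census reports carrier prevalence,
per-strain array counts, and array-level spacer medians by group (the
median of array spacer counts, mean-of-central-values for even counts). An
array counts as **prophage-embedded** only when fully contained within a
call — the stricter reading of partial overlap, chosen so that boundary
jitter cannot manufacture embeddings. Plasmid-borne arrays keep an
`on_plasmid` flag and count toward strain totals.

## Cell geometry and burden per cell

Volumes and surface areas come from the classical shape approximations:
rods are cylinders (V = pi r^2 L, closed area 2 pi r^2 + 2 pi r L), cocci
spheres, ovoid cells general ellipsoids with the Knud Thomsen surface
approximation (p = 1.6075), which collapses exactly to 4 pi r^2 for equal
semi-axes and is accurate to ~1.2% elsewhere. Two deliberate departures
from common hand-calculation habits: the exact 4/3 replaces the truncated
1.333 (relative error 2.5e-4; `legacy_constant = TRUE` restores 1.333 for
regression against older tables), and the dimensionally inconsistent
"2 pi r^2 * pi r L" sometimes seen for cylinder area is replaced by the
closed-cylinder formula. Size bins are small < 1, middle 1-2.5, big
> 2.5 um^3 (areas: 6 and 12 um^2), with boundary values assigned to the
middle class.

Burden is reported two ways: **prophage bp per um^3 of cell** and
**prophage density** (prophage bp / genome bp). The two deliberately
dissociate — a lineage of large cells with ordinary genomes ranks high on
density and low per volume — and density is defined as the genome fraction
because that is the only reading consistent with large-celled lineages
showing simultaneously the lowest per-volume DNA and the highest density.
A missing cell volume marks the per-volume measure unavailable rather than
zero.

## Homology network

Homologs are defined on all-vs-all protein alignment hits (BLAST-style
12-column tabular): percent identity >= 30 (inclusive), e-value <= 1e-4
(inclusive), alignment length > 20. Identity is used for the "similarity"
threshold because tabular output carries no separate similarity column.
Self-hits are dropped, reciprocal duplicates collapse to one undirected
pair, and within-prophage pairs are flagged internal and excluded from
edges. Edge weight is the number of distinct homologous ORF pairs between
two prophages; edges with weight >= 10 are **significant** (the inline
">= 10" reading is preferred over a strict "more than 10"). Because
"N homologous proteins" is ambiguous between pairs and distinct ORFs, both
per-node counts are reported. A prophage left `unclassified` by the
structural-module classifier with fewer than 10 homolog pairs is flagged a
**remnant candidate** — a report for user judgement, not a verdict.

Annotation confidence is two-tier: `high` requires both e-value < 1e-4 and
alignment length > 100; `low` is the complement (the two published tiers
are not logically exhaustive, so low is defined as not-high). The keyword
census counts lifecycle markers (terminase, integrase, nuclease,
transposase, DNA primase, lysin) and structural markers (portal, head,
capsid, tail, coat, baseplate) with case-insensitive **whole-word**
matching — substring matching would count "overhead" as "head"; precision
was preferred since the original matching rule is unstated.

Synteny between two regions is visualised by an exact k-word dotplot
(default k = 10, both strands; words containing N never match;
reverse-complement matches are reported in forward coordinates of the
second sequence). For independent random sequences at k = 12 the expected
number of matches for 1 kb sequences is (991^2)/4^12 < 0.1, so any visible
diagonal is signal.

## Marker-gene phylogeny

The phylogeny stage consumes a curated protein multiple alignment (the
alignment itself is upstream). Distances are **p-distances with pairwise
gap deletion**: a curated alignment retains only unambiguous columns, so
discarding whole columns for a single gapped taxon (complete deletion)
would waste signal; no substitution-model correction is applied because
none is implied by an uncorrected-divergence scale. Trees are built by
Saitou-Nei neighbor-joining; negative branch-length estimates are clamped
to zero and flagged. Support comes from 100 bootstrap column resamples
(default), counting how often each reference split recurs; supports below
50% are suppressed in the display newick but retained in the table.
Outgroup rooting is display-only. Given a seed, supports are reproducible.

## Association statistics

All statistics use complete-case deletion; the package never imputes
missing traits. An `exclude` argument on the PCA reproduces analyses that
drop extreme-volume strains.

* **Spearman correlation** uses average ranks for ties. The two-sided
  p-value is an exact permutation enumeration (all n! orderings) for
  n <= 9 and the t approximation t = r sqrt((n-2)/(1-r^2)) otherwise. The
  exact p includes the observed statistic in the tail
  (P(|rho_perm| >= |rho_obs|)), the standard permutation convention.
* **Wilcoxon rank-sum** is exact (full null enumeration) when the combined
  n is at most 12 with no ties, otherwise the normal approximation with
  tie and continuity corrections.
* **2x2 contingency**: the sample odds ratio ad/bc with the Woolf logit
  95% CI; the Haldane-Anscombe +0.5 correction is applied (and flagged)
  when any cell is zero. The p-value is Fisher's exact two-sided test on
  the uncorrected table. The sample OR is reported rather than the
  conditional MLE because it is the estimator the field's summary tables
  print.
* **PCA** is correlation-matrix PCA (columns standardized) over the eight
  trait variables (prophage count, CRISPR count, pH, T, GC%, doubling
  time, cell volume, genome size); percent variance is eigenvalue share,
  and each loading vector is oriented so its largest-magnitude entry is
  positive — a sign convention only.
* **Family aggregation** sums carriage per host family and rank-correlates
  total prophages against total CRISPR arrays across families (>= 4
  families required).

No multiple-testing correction is applied: the battery mirrors an analysis
style in which each association is reported with its own raw p-value.

## The synthetic-data generator

Every pipeline input can be generated in code, with the statistical
structure the analysis assumes. The defaults are the study conditions of
the SRP survey and are not tuned per run:

| parameter | default | rationale |
|---|---|---|
| strains | 91 | survey panel size |
| lysogen fraction | 0.56 | lysogen prevalence |
| prophages per lysogen | zero-truncated geometric, p = 51/81 | mean 81/51 ~ 1.59 |
| prophage length | lognormal, sdlog 0.55, mean 56,120 bp | observed mean prophage size |
| genome length | Normal(3.9 Mb, 0.7 Mb), > 1 Mb | SRP genome sizes |
| CRISPR carriers | 0.78 (zero-inflated Poisson, lambda 2.5) | carrier prevalence; counts ~1-11 |
| spurious level-1 arrays | Poisson(0.4)/strain | removed by the evidence filter |
| spacers per array | 1 + NB(mu 28, size 4) | spacer medians in the mid-20s to 30s |
| detector sensitivity | 0.98 / 0.98 | near-complete detectors |
| false positives | 0.05 per Mb per detector | rare, rarely concordant |
| boundary jitter | Normal(0, 150 bp), rounded | detector windowing noise |
| volume-prophage Spearman | 0.32 | observed volume association |

Cell volume is coupled to the prophage count by a Gaussian copula: the
count's average rank (tie-block midpoint) maps to a standardized latent
normal score, the latent Pearson correlation is 2 sin(pi rho / 6), and the
volume is the lognormal quantile of the correlated score. Coupling to the
tie-block midpoint rather than to a within-block uniform matters: with
~44% prophage-free strains, a coupling that spends correlation ordering
volumes inside tie blocks attenuates the realized (average-rank) Spearman
well below its target, while the midpoint coupling recovers target rho
within 0.01 at n = 60 in the package's own calibration tests.

Homology hits are generated around planted gene-content clusters: within-
cluster prophage pairs share a configured number of filter-passing ORF
pairs (default 12) and between-cluster pairs fewer (default 2), plus
decoy hits that each fail exactly one filter criterion. The protein
alignment simulator evolves an ancestral sequence down a random tree
(per-site substitution probability min(0.75, edge length)) and is labelled
synthetic: it exercises the distance/NJ/bootstrap machinery and makes no
claim to empirical substitution realism.

What passing tests on synthetic data do and do not show: they establish
that the pipeline's operations implement their definitions (oracle
equivalence, pipeline identity under perfect detectors, parameter
recovery), not that any biological conclusion transfers. The generator
implants independent, non-overlapping prophages with lognormal lengths and
habitat-independent traits; real genomes have nested and degraded
elements, detector errors correlated with genomic context, and
phylogenetically autocorrelated traits, none of which are modelled.

## Numerical conventions and problem sizes

Degenerate inputs are errors, not silent defaults: empty censuses,
correlations with fewer than 4 complete pairs or zero variance, PCA with
fewer than 3 complete rows or a constant column, distance matrices with a
taxon pair sharing no ungapped columns, odds ratios with a zero margin.
Validation of interval tables rejects `start >= end` at read time with the
offending line reported for the pipeline's TSV dialects.

The test and acceptance workloads use deliberately moderate problem sizes
— 500 random interval instances for the consensus oracle, every two-sample
split of a ten-value pool for the exact Wilcoxon oracle, all 2x2 tables
with margins up to 10, 200 random additive trees of up to 8 taxa, 200
replicates per copula target, 100 seeded pipeline-identity simulations —
chosen to give stable Monte Carlo means while keeping a full run in the
low minutes on one core.

## Known limitations

* Consensus coordinates inherit the detectors' windowing; neither
  intersection nor union is the "true" prophage boundary.
* The census treats detector outputs as exchangeable; no detector-specific
  error model is fitted.
* Remnant classification is a heuristic gate (unclassified + < 10
  homologs) and deliberately stops short of calling degradation.
* The exact Spearman permutation is enumerated only to n = 9 (9! =
  362,880 orderings); beyond that the t approximation is used, which is
  slightly anticonservative at n just above the switch.
* p-distances saturate for deep divergences; the NJ stage is intended for
  within-guild marker comparisons, not deep phylogeny.
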