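---
title: "Resolving HIF isoform dependence in Vhl-null proximal tubular cells: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving HIF isoform dependence in Vhl-null proximal tubular cells: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Loss of the von Hippel-Lindau tumour suppressor (*Vhl*) stabilizes both
isoforms of the hypoxia-inducible factor alpha subunit, HIF1A and HIF2A
(*Hif1a*/*Epas1*), and rewires the transcriptome of renal proximal tubular
(PT) cells. The central analytic question this package addresses is
*epistasis by knockout contrast*: for every gene whose expression changes
after *Vhl* inactivation, which HIF isoform is required for that change?
The experimental design crosses a *Vhl* knockout with knockouts of either
or both isoforms, yielding five genotypes:

* `ConKO` — *Vhl*-competent control
* `VKO` — *Vhl*-null
* `VHKO` — *Vhl*- and *Hif1a*-null
* `VEKO` — *Vhl*- and *Epas1*-null
* `VHEKO` — *Vhl*-, *Hif1a*- and *Epas1*-null

with tagged (tdTomato) recombined cells sampled **early** (weeks) or
**late** (months) after induction, four mice per genotype per cohort, and
both sexes represented. `hifsort` implements the full downstream pipeline —
quality control, cell annotation, pseudo-bulk differential expression, the
isoform classification ledger, temporal program calling, anchored program
scoring, enrichment testing, and the spatial clonal-neighborhood
statistics — together with a synthetic-data generator that plants known
ground truth so that every stage is testable without any sequencing data.

# Cell-level quality control

Cells are kept when all three filters pass, evaluated jointly (not
sequentially) against pre-filter statistics:

* detected genes per cell strictly greater than 200;
* mitochondrial read fraction strictly below 0.5 — deliberately permissive
  because PT cells are mitochondria-rich;
* detected genes strictly below 3 times the per-sample (per-mouse) median
  of detected genes, a doublet guard.

The per-sample median is computed before any cell is removed; because the
filters are presented as one set, we treat them as one set. With medians
recomputed, a second application removes no further cells, and the suite
asserts this idempotence. Mitochondrial genes are recognized by a
configurable id prefix (default `mt-`).

# Cell annotation

**Cell type** is assigned by rank-ceiling signature scoring. Within each
cell, genes are ranked by descending expression with average ranks for
ties (all unexpressed genes therefore share one bottom rank); signature
gene ranks are clipped at `max_rank + 1` (default `max_rank = 1500`) and
converted to a normalized Mann-Whitney statistic in [0, 1]. Because only
ranks enter the score, it is invariant to any monotone transform of
expression, and scores of different signatures are comparable within a
cell; each cell takes the label of its top-scoring marker set, with exact
ties broken lexicographically and flagged. PT S2 and S3 markers are
sex-dimorphic, so those sets carry sex-specific gene lists and each cell is
scored against the list matching its sex; S1 uses a unisex list.

**PT class** (the A/B expression dichotomy within each segment) uses the
classic binned-control module score: genes are binned into equal-frequency
bins (default 100) by average log-normalized expression (log1p of counts
per 10,000), each signature gene draws control genes from its own bin
(default 50 per gene, sampled without replacement, seeded, logged in the
result so toy examples are exactly checkable), and the score is the mean
signature expression minus the mean control expression. Cells with Module
A score strictly above 0.125 are Class A; the threshold is treated as a
plain parameter, as no derivation for it is available. When a bin holds
fewer genes than requested controls the draw falls back to sampling with
replacement and warns; the synthetic gene space is small, so the bundled
configurations use 20 bins and 20 controls — a fixture-scale choice, not a
change of method.

# Pseudo-bulk differential expression

All differential expression is performed per PT identity with the mouse,
not the cell, as the biological replicate: raw counts are summed over each
mouse's cells in the stratum (mice contributing fewer than 10 cells are
excluded with a warning). Size factors are median-of-ratios (geometric-mean
reference over genes positive in all samples, normalized to geometric mean
one, with a total-count fallback).

Each gene is fitted with a negative-binomial log-link GLM, design
`~ sex + group` and offset `log(size factor)`, on the samples of the two
contrasted levels; sex is dropped automatically (with a warning) when
constant or confounded. The Wald statistic of the contrast coefficient
gives a two-sided normal p value, BH-adjusted across genes with no
independent filtering. Genes are *regulated* when `|L2FC| > 1` and
adjusted p < 0.05, both strict.

Dispersion is estimated per gene by method of moments on normalized
counts and stabilized by empirical-Bayes shrinkage toward a fitted
mean-dispersion trend `alpha(mu) = a0 + a1/mu`; this captures the behavior
of heavier machinery at the scale of a pseudo-bulk design without
replicating any particular tool bit-for-bit. Three implementation details
matter for calibration and are asserted by simulation:

* the moment estimator subtracts `mu * mean(1/sf)` (the shot-noise term of
  normalized counts), not `mu`;
* the variance is pooled **within design cells** (sex x group), falling
  back to the contrast groups when the cells lack replication — otherwise
  sex-dimorphic genes masquerade as dispersed genes and inflate the trend;
* the trend is fitted to binned means of the *unfloored* estimates
  (flooring first would select positive noise and bias the trend up), and
  the log-scale shrinkage (prior log-variance 0.25, observation variance
  `trigamma(df/2)`) corrects the Jensen bias of the log of a
  mean-unbiased estimate; negative moment estimates enter the shrinkage
  floored at 5% of the trend, encoding "below trend" rather than "zero".

No fold-change shrinkage is applied: the classification thresholds act on
the raw maximum-likelihood coefficients. Strata missing a genotype fail
loudly rather than being silently dropped.

# The isoform classification ledger

For one identity, four contrasts are computed at the late timepoint:
`VKO vs ConKO`, `VHKO vs VKO`, `VEKO vs VKO`, `VHEKO vs VKO`. A gene is
**Vhl-dependent** when regulated in the first. For each knockout contrast
the gene is *dependent* on the deleted gene(s) when the contrast is
significant (adjusted p < 0.05; no additional magnitude gate), the sign
opposes the `VKO vs ConKO` change, and its magnitude is strictly more
than half of the `VKO vs ConKO` magnitude. The category is then a pure
function of the three flags:

| *Hif1a*-dep | *Epas1*-dep | double-dep | category |
|---|---|---|---|
| yes | yes | — | `HIF1A_or_HIF2A` |
| yes | no | — | `HIF1A_alone` |
| no | yes | — | `HIF2A_alone` |
| no | no | yes | `HIF1A_plus_HIF2A` |
| no | no | no | `ambiguous` |

The suite proves this table total and deterministic by exhaustive
enumeration against an independently coded rule evaluator.

**Temporal classes** use `VKO vs ConKO` at the early timepoint (early
regulation) and late-vs-early within VKO but not within ConKO (adaptive
regulation); genes qualifying as both are flagged `both_excluded` and
barred from program scoring. The same regulation thresholds are applied in
every contrast and are exposed as parameters.

**Pooling** takes the union of isoform-specific calls across identities; a
gene called HIF1A-specific in one identity and HIF2A-specific in another
(same direction) is reported as a conflict and excluded from both pooled
sets, which are therefore disjoint. A Spearman diagnostic correlates the
`VHEKO vs VKO` against the `VKO vs ConKO` fold changes over a gene subset;
fully HIF-dependent regulation approaches complete anti-correlation.

# Program scoring

Programs (e.g. "HIF2A adaptive up") are scored per identity with the
binned-control score and then anchored: an affine transform per identity
places the reference cohort median exactly at 0 and the target cohort
median exactly at +1 (up programs) or -1 (down), after which identities
are amalgamated. Anchor cohorts are configurable by genotype and
optionally timepoint (e.g. reference "ConKO early", target "VKO late").
The anchor equalities are exact (medians commute with affine maps) and the
suite asserts them as equalities, not tolerances. Identities whose two
anchor medians coincide cannot be scaled and are skipped with a warning.
Anchoring per identity before pooling is a deliberate choice — it
guarantees the pooled cohorts keep their anchor property regardless of
identity composition.

Bulk cohorts (tumor/normal expression matrices) are scored by z-scaling
each gene across all samples and summing over set genes per sample;
zero-variance genes are dropped with a warning, and the score is invariant
to per-gene affine transforms. Group differences use Kruskal-Wallis with
Bonferroni-corrected pairwise Dunn comparisons.

# Enrichment

Over-representation uses the one-sided hypergeometric tail on the 2x2
overlap table with BH correction across sets; sets outside the 50-1000
size bounds (after intersection with the universe) are excluded before
testing. GSEA is the weighted Kolmogorov-Smirnov running sum (weight
exponent 1 on the absolute ranking statistic); the null is gene-label
permutation (seeded), NES divides by the mean |null ES| of the same sign,
and the two-sided permutation p carries the +1 correction. Permutation
rather than analytic p values keeps the estimator exact at the scale this
package targets. Term profiles can be ordered by Ward (`ward.D2`)
hierarchical clustering on Euclidean distances of average member fold
changes. Ortholog mapping and GO graph handling are out of scope: users
supply pre-mapped GMT collections.

# Spatial clonal neighborhoods

Per-nucleus tissue tables carry coordinates in microns, region labels,
nucleus areas and stain intensities. Nuclei outside [15, 200] um^2 are
excluded (bounds inclusive, since the exclusion rule is strict). Positivity
is a strict threshold on intensity. The clonality statistic counts, for
every tagged cell, the other tagged cells within a 16 um internuclear
radius — Euclidean, centroid-to-centroid, boundary inclusive (the radius is
motivated by near-total coverage: almost every cortical cell has some
neighbor within 16 um, which the synthetic cortex reproduces). A bucketed
grid index accelerates counting and is asserted to equal the all-pairs
scan exactly. Per mouse, counts are summarized as a frequency vector
(default bins 0,1,2,3,4,>=5; configurable) and a mean.

Frequency distributions are compared by one-way MANOVA on the per-mouse
proportion vectors: constant bins are dropped, one remaining bin is
dropped for compositionality (with two informative bins this degenerates
to a univariate comparison, for which the same formulas hold), Wilks
Lambda = det(E)/det(E+H) is converted to p by Rao's F approximation, and
pairwise comparisons are Bonferroni-adjusted. Medians are compared with
Kruskal-Wallis (tie-corrected) plus Dunn z statistics with the tie term,
Bonferroni-adjusted over the requested pairs.

# The synthetic-data generator

The generator is the package's study stand-in, not a test shim. Counts are
negative binomial (`Var = mu + alpha mu^2`, default `alpha = 0.4` at the
cell level) around a multiplicative mean model: per-gene log-normal
baseline; marker blocks (60 genes per PT segment, sex-specific for S2/S3)
elevated 8-fold in their own cells; Module A/B blocks (80 genes each)
elevated 4-fold in their class; 50 sex-dimorphic genes at +1 log2 in
males; a per-mouse log-normal scalar (sd 0.15 on the log scale) creating
the within-genotype correlation that motivates pseudo-bulking; and a
per-cell log-normal library factor (sdlog 0.25). Planted programs carry
|L2FC| = 2 in `VKO vs ConKO` by default, 40 genes per isoform category;
the isoform truth fixes which genotypes express the effect (e.g. a
`HIF1A_alone` program is active in VKO and VEKO only), and adaptive
programs act only at the late timepoint while early programs persist.
Defaults mirror the study design: five genotypes, four mice per genotype
per cohort, six PT identities at 200 cells per identity per mouse. The
end-to-end fixtures use two identities — the identity dimension
multiplies runtime but not information, since programs are planted
identically across identities.

Known limitations, stated deliberately: genes are generated independently
(no co-expression structure), there are no doublets or ambient RNA, and
the spatial process is a 2-D minimum-spacing point pattern with disc
placement of daughters — sufficient to exercise the stage logic and the
statistics, but not a model of tissue. Passing on synthetic data therefore
demonstrates correctness of the computations and calibration under the
stated model, not robustness to every artefact of real droplet data.

Magnitudes of clonal expansion and elimination are not published as
numbers, only their statistical signatures; the generator exposes them as
free parameters with defaults chosen to be biologically plausible
(expected one daughter per tagged *Vhl*-null cell at the late timepoint,
half of tagged cells eliminated in the papilla when HIF1A is intact,
daughters within 16 um of parents, 5 um minimum internuclear spacing).

# Numerical and design choices

* Strict inequalities are used wherever the decision rules state them
  (>200 genes, >50%/<20% marker fractions, >0.125 class score, |L2FC|>1,
  "more than half").
* The per-sample median for the QC gene-ceiling uses pre-filter medians.
* Rank ties take average ranks; the rank ceiling makes the treatment of
  zeros nearly immaterial.
* Degenerate inputs fail loudly (`missing contrast`, `empty gene set`,
  `field too small`) or are flagged (all-zero genes get `l2fc = 0, p = 1`).
* Every stochastic step takes an explicit seed, and the pipeline derives
  per-stage seeds from one master seed, so identical configuration and
  seed reproduce byte-identical output tables.
* Problem sizes in the bundled checks (two identities, 2,000 genes, 100
  replicate strata for power, 50 replicates for spatial power) are the
  package's chosen desk-scale study conditions; sensitivity floors
  (>= 0.80 per category), the confusion ceiling (<= 5%), and calibration
  bands (raw p < 0.05 fraction in [0.03, 0.07], KS uniformity p > 0.01)
  are asserted at these sizes in the test suite and recomputed by
  `scripts/acceptance.R`.

# Interfaces

The package is the interface: tidyverse-style functions that take and
return tibbles, `autoplot()` methods for each result type, and
`tidy()`/`glance()` for fitted objects. `run_pipeline()` orchestrates the
stages from a YAML-serializable configuration and writes TSV outputs plus
a manifest (package version, seed, parameter hash) sufficient to reproduce
any table byte-identically. Real deposited matrices can be read through
`read_cell_matrix()` (MatrixMarket + TSV sidecars), but no test or check
requires a download.
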