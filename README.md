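# hifsort

Resolving which transcriptional consequences of *Vhl* loss in renal
proximal tubular (PT) cells depend on HIF1A, on HIF2A, on either, or only
on both — from tagged single-cell counts and tissue nucleus tables through
to classified gene programs and spatial clonality statistics.

Loss of the von Hippel-Lindau tumour suppressor stabilizes both isoforms
of hypoxia-inducible factor alpha. The experimental design this package
analyzes crosses a conditional *Vhl* knockout with knockouts of either or
both isoform genes, giving five genotypes (ConKO control, VKO =
*Vhl*-null, VHKO = +*Hif1a*-null, VEKO = +*Epas1*-null, VHEKO = both),
sampled early (weeks) or late (months) after recombination, four mice per
genotype, both sexes. `hifsort` is written for computational biologists
running that style of genetic-epistasis transcriptomics: it implements

* cell QC (genes/cell > 200, mito fraction < 0.5, genes < 3x per-mouse
  median; strict, joint, pre-filter medians);
* cell-type assignment by rank-ceiling (UCell-style, `maxRank = 1500`)
  signature scores with sex-matched marker lists, and PT Class A/B
  assignment by binned-control module score (> 0.125 = Class A);
* per-mouse pseudo-bulk negative-binomial Wald differential expression
  with design `~ sex + genotype`, median-of-ratios size factors, and
  trend-shrunken method-of-moments dispersions;
* the isoform classification ledger: a *Vhl*-dependent gene
  (|L2FC| > 1, adjusted p < 0.05 in VKO vs ConKO) is *Hif1a*-dependent if
  *Hif1a* co-deletion reverses it significantly, in the opposite
  direction, by **more than half** the magnitude — likewise for *Epas1*
  and the double knockout — and the flag triple maps to
  `HIF1A_alone` / `HIF2A_alone` / `HIF1A_or_HIF2A` / `HIF1A_plus_HIF2A` /
  `ambiguous`;
* early vs adaptive program calling from timepoint contrasts, with
  double-qualifying genes excluded;
* program scoring scaled to anchors (reference-genotype median = 0,
  target median = +1/-1, exactly, per identity), dedifferentiation
  scoring, bulk-cohort summed z-scores, hypergeometric marker enrichment;
* over-representation (one-sided hypergeometric, 50-1000 size bounds, BH)
  and permutation GSEA (weighted KS running sum, seeded label
  permutations);
* spatial clonality: nucleus area filters (15-200 um^2), intensity
  thresholding, tagged-neighbor counts within 16 um (grid-indexed, equal
  to the all-pairs scan), Wilks-Lambda MANOVA on per-mouse frequency
  vectors, Kruskal-Wallis with Dunn post hoc;
* a synthetic-data generator planting known isoform and timing truth, so
  the whole pipeline is testable end to end with no downloads.

## Worked example

```r
library(hifsort)

# A small synthetic cohort: 5 genotypes x 2 mice, two PT identities
sim <- simulate_counts(sim_config(
  n_mice_per_genotype = 2, timepoints = "late", cells_per_mouse = 120,
  identities = default_identities()[1:2, ], genes_total = 700, seed = 42))

m <- apply_qc(sim$matrix)
m <- annotate_cells(m, sim$markers, sim$module_a,
                    max_rank = 500, n_bins = 20, n_ctrl = 20)

pb  <- aggregate_pseudobulk(m, "PT_S1_A")
de  <- fit_de(pb, c("genotype", "VKO", "ConKO"))
calls <- classify_dependence(
  de,
  fit_de(pb, c("genotype", "VHKO", "VKO")),
  fit_de(pb, c("genotype", "VEKO", "VKO")),
  fit_de(pb, c("genotype", "VHEKO", "VKO")))
glance(calls)
```

```
#> # A tibble: 2 × 7
#>   identity direction HIF1A_alone HIF1A_or_HIF2A HIF1A_plus_HIF2A HIF2A_alone
#>   <chr>    <chr>           <int>          <int>            <int>       <int>
#> 1 PT_S1_A  down               20             18               20          21
#> 2 PT_S1_A  up                 20             20               20          20
#> # i 1 more variable: ambiguous <int>
```

Each row counts the *Vhl*-dependent genes of one direction by inferred
isoform category; the generator planted 20 genes per category per
direction, and at this deliberately small cohort size (2 mice per
genotype) recovery is near-perfect — two borderline down-regulated genes
shift between the neighbouring `HIF1A_or_HIF2A` and `HIF2A_alone`
categories. The planted `HIF_independent` genes correctly land in
`ambiguous`, since no knockout reverses them. `autoplot(de)` draws the
volcano,
`autoplot(calls)` the category composition, and

```r
ss <- score_and_scale(m, sim$truth$gene_id[sim$truth$isoform_truth == "HIF2A_alone" &
                                           sim$truth$direction == "up"],
                      direction = "up", n_bins = 20, n_ctrl = 20)
glance(ss)
```

shows the anchored program medians per genotype — with this run: ConKO
exactly 0, VKO exactly 1, VHKO 1.08, VEKO -0.06, VHEKO -0.02. That is the
HIF2A signature: deleting *Hif1a* leaves the program fully expressed,
deleting *Epas1* abolishes it.

`run_pipeline(pipeline_config(...))` chains all stages from one seeded
configuration and writes `calls.tsv`, score tables, DE tables and a
manifest whose parameters and seed reproduce every table byte-identically.

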