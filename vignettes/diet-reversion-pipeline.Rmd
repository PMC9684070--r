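---
title: "Quantifying obesity-induced and diet-reversible endothelial transcriptome changes"
author: "ecrestore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying obesity-induced and diet-reversible endothelial transcriptome changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Endothelial cells (ECs) line every vascular bed and adopt strongly
organ-specific transcriptional programs. Diet-induced obesity perturbs these
programs in an organ- and vessel-subtype-specific way, and a reversion diet
(switching obese animals back to standard chow) undoes some, but not all, of
the perturbation. `ecrestore` implements the quantitative core of that
analysis as a reusable, tested pipeline operating on single-cell RNA-seq
count matrices:

1. cell/gene quality control and library-size log-normalization;
2. marker-panel annotation of arterial (art), capillary (cap) and venous
   (ven) EC subtypes;
3. per-gene Wilcoxon rank-sum differential expression with
   Benjamini–Hochberg (BH) correction and natural-log fold changes;
4. downsampling-equalized DEG counting across clusters of unequal size;
5. chow-standardized restoration classification under the reversion diet;
6. cross-organ fold-change concordance and consistency ranking;
7. EC population-shift quantification and platelet-positive EC detection;
8. a join of mouse DEGs against human GWAS-catalog risk genes.

Because the study's raw data are not redistributable at package scale, every
stage is exercised end-to-end against a bundled negative-binomial simulator
with planted, recoverable effect structure (`synth_config()`,
`generate_dataset()`).

## Study design encoded in the data model

A `CellDataset` carries a sparse cells × genes UMI matrix plus per-cell
metadata: `organ`, `cluster`, `diet` ∈ {chow, wd, rev}, `timepoint_months`
∈ {3, 4, 6} and `animal`. The design constraint that the reversion arm
exists only at 4 and 6 months (animals are fed a Western diet for 3 months,
then switched) is validated at construction. On disk the package reads and
writes the 10x-style triplet (Matrix Market coordinate integer,
features × cells, as CellRanger emits) plus a metadata TSV keyed by
barcode; in memory everything is cells × genes.

## Quality control and normalization

Cells are removed when they have fewer than 500 or more than 6,000 detected
genes, more than 25,000 UMIs, or more than 20% mitochondrial UMIs
(case-sensitive `mt-` prefix, mouse nomenclature). All four are *strict*
inequalities on the removal side: a cell at exactly 500 genes, 25,000 UMIs
or 20% mitochondrial content is retained. Cell criteria are evaluated on
the pre-filter matrix. Genes are dropped when they have zero counts across
the *retained* cells; evaluating the gene rule after cell selection is what
makes `qc_filter()` idempotent — a second pass removes nothing, so QC'd
data can be re-QC'd harmlessly in a file-based pipeline.

Normalization is `ln(1 + count / libsize × s)` with the per-cell UMI total
as library size and scale factor `s = 10^4` by default — the standard
log-normalization of UMI data, on the natural-log scale throughout. The
scale factor is configurable since it is a convention, not an estimate.

## Subtype annotation

Subtypes are assigned per cell as the argmax over marker panels of the mean
normalized expression of each panel's genes present in the data (art:
Fbln5, Gkn3, Hey1, Mgp; cap: Car4, Rgcc; ven: Vcam1, Vwf; organ-specific
extensions can be appended). Ties are broken by panel order and flagged.
Graph-based clustering is out of scope here, so when cluster labels are
available annotation can instead majority-vote within clusters
(`annotate_subtypes(..., clusters = )`), which mirrors cluster-level
assignment and is markedly more accurate than per-cell calls.

## Differential expression

For a contrast between two disjoint cell groups within one
organ × subtype × timepoint, every gene detected (nonzero) in at least one
cell of either group is tested; no minimum-detection or fold-change
pre-filter is applied by default (both exist as arguments, off). This
matters: DEGs are called down to |logFC| > 0.1, below common tool
pre-filters.

*Test.* `wilcoxon_rank_sum()` uses midranks for ties. For tie-free samples
with `n1 + n2 ≤ 12` (configurable) the p-value comes from the exact null
distribution of the Mann–Whitney U; otherwise a normal approximation with
tie-corrected variance and continuity correction is used. The approximation
is accurate in the regime where it is used — abundant ties and group sizes
in the tens to thousands — but it cannot track the few-atom exact null at
very small group sizes: the measured worst-case absolute error against full
enumeration over all tie-free partitions with `n1 + n2 ≤ 12` is 0.13 when a
group has a single observation, 0.04 with minimum group size 3, and ≤ 0.02
once both groups have ≥ 5 observations. This is a property of any smooth
approximation to a discrete distribution with a handful of support points
(for `n1 = 1` the null is uniform and two-sided p-values step by
`2/(n2+1)`), which is precisely why the exact path exists and covers that
regime by default.

*Multiplicity.* BH is applied per contrast across exactly the tested gene
set (`bh_adjust()`, a validated front-end to the standard step-up
procedure), matching per-cluster DEG reporting; no global correction across
organs is performed.

*Fold change.* `lfc = ln(mean(e^x1 − 1) + 1) − ln(mean(e^x2 − 1) + 1)`:
de-logged group means with pseudocount 1 on the natural-log scale. The
pseudocount shrinks fold changes of weakly expressed genes toward zero; the
`pseudocount = 0` variant is the unbiased plain log mean ratio and is used
by the simulator's recovery helper (`empirical_group_lfc()`).

*Significance.* `adj_p < 0.05` and `|lfc| > 0.1`, both strict.

## Downsampling-equalized DEG counting

DEG counts scale with statistical power and hence with cluster size, so raw
counts are not comparable across clusters. `count_degs_downsampled()`
subsamples every group of every contrast, without replacement, to a common
size — by default the smallest group across contrasts (the study's design
downsampled to its smallest cluster, 73 cells) — and counts significant
genes. With `n_draws > 1` the per-contrast count is the median across
draws; the median is robust to occasional outlier draws. All draws are
seeded and the seed is logged.

## Restoration under the reversion diet

For each organ × subtype, the obesity DEG set is taken from the 6-month
WD-vs-chow contrast. Both the sustained-WD and the reversion arm are
standardized to the chow control *at the same timepoint*
(`standardize_to_chow()`), making the comparison unit-free and robust to
timepoint drift in the controls. A DEG is **restored** when its
chow-standardized reversion fold change is closer to chow than to
sustained WD:

    restored  ⇔  |lfc_rev| < |lfc_rev − lfc_wd|

computed on logFCs rather than raw group means; the two formulations differ
only through the pseudocount, and the logFC form inherits the
standardization stated above (the mean-ratio variant is available via
`pseudocount = 0` for sensitivity analysis). Equality within `1e-12` is
flagged as a tie and conservatively classified *not* restored (persistent).
The classification is scale-consistent: rescaling both fold changes by any
positive constant leaves every flag unchanged. DEGs undetected in the
reversion arm are excluded and counted, never imputed.
`restored_proportions()` reports per-direction fractions, with a direction
that has no genes reported as undefined (`NA`), not zero.

## Cross-organ statistics

*Concordance* (`deg_concordance()`): the gene universe is the union across
organs of genes with `|lfc| > 0.1` in any table; each organ pair is
correlated (Pearson r) over the universe genes measurable in both members.
Pairs sharing fewer than 3 genes are undefined.

*Consistency ranking* (`consistency_ranking()`): genes with a computable
fold change in **every** organ are ranked by mean logFC across organs;
genes with mean `|lfc| > 0.2` (strict) are kept, split into up- and
downregulated lists. The result is invariant to organ ordering.

*Population shifts* (`population_shifts()`): per-cluster cell fractions in
condition and control, and their log2 ratio. Clusters absent from one arm
are reported with an undefined ratio and a zero-fraction flag, never
dropped or patched with a pseudo-fraction. The highlight threshold on
|log2 ratio| is per-figure presentation (0.5 default, 0.3 where stated).

*Platelet-positive ECs* (`platelet_positive_fraction()`): a cell is
positive when any single one of Pf4, Ppbp, Nrgn exceeds 1 UMI (i.e. ≥ 2
counts of one gene; counts are not summed across the triple). The strict
">1" reading is kept and the threshold is exposed, since "≥1" is a
plausible alternative reading.

*Cluster z-scores* (`cluster_zscores()`): per-gene cluster means are
z-scored across clusters. The population standard deviation (denominator =
number of clusters) is the default — the convention is not fixed by the
heat-map definition, so it is configurable — and genes constant across
clusters get a flagged all-zero row.

## GWAS integration

`read_gwas_catalog()` retains SNP–gene–trait records with association
`p ≤ 10⁻⁵`, expands multi-gene rows, and drops (counting) unparseable
p-values; the gene column is configurable because catalog exports differ on
mapped vs reported genes. `link_degs_to_gwas()` aggregates each gene's
qualifying SNPs by the *minimum* p (one point per gene, the strongest
association), maps human symbols to mouse — an explicit ortholog table
first, then the capitalization heuristic (APOE → Apoe) validated against
the DE gene universe — and joins on the DE table, highlighting genes with
`|lfc| > 0.1`. Child traits are excluded by exact trait-label matching;
no ontology traversal is attempted (documented limitation).

## The synthetic generator

`generate_dataset()` draws UMI counts as negative binomial with mean
`base_mean × libsize_factor × marker_mult × e^effect` and common dispersion
θ (default 2; variance `m + m²/θ`), log-normal per-gene base means
(location `ln 0.2`, scale 1) and log-normal library-size factors (sd 0.3).
Marker genes get a fixed base mean (1.0 — canonical markers are reliably
expressed; a random baseline would let panel-baseline imbalance mask the
enrichment signal) and are multiplied by `marker_fold` (default 10×) in
their own subtype. Per organ × subtype, an exact-count fraction `frac_de`
of non-marker genes carries a planted effect, half up and half down,
magnitudes uniform over `effect_size_lfc`; an exact-count fraction
`frac_restored` per direction loses its effect under the reversion arm
(`restored_gamma` plants partial restoration for boundary studies).
Platelet genes are zero in all cells except an exact-count spiked fraction,
which receives ≥ 2 counts of one platelet gene — so spike-fraction recovery
is exact, not approximate. Everything is deterministic given the seed.

What the generator does **not** emulate: doublets, ambient RNA, batch or
animal effects, organ-specific biology beyond marker enrichment, and
library-composition coupling beyond what the NB model induces (planting
balanced up/down effects keeps composition shifts to a few percent, visible
as a small shrinkage of recovered fold changes). Passing tests on this
generator therefore validates the *statistical machinery* — calibration,
power, recovery, equalization — not robustness to those artefacts.

## Problem sizes and numerical choices

The package's property checks run at sizes chosen to make each property
measurable above Monte-Carlo noise while remaining desk-scale:

- type-I error: 2,000 genes × 300 cells/group, null effects, 20 seeds;
- restoration recovery: 200 planted DEGs (|lfc| ∈ [0.5, 1],
  70% restored) at 300 cells/group, 10 seeds — recovered proportions land
  within a few points of 0.7 in both directions;
- downsampling equalization: 73 vs 1,000 cells/group with identical
  planted effect sets. Strong effects (|lfc| ∈ [1.5, 2], the scale of the
  strongest obesity responders) are planted here because the 73-cell
  cluster contributes a single realization — no draws can average away its
  dataset-level count noise — and weaker effects would leave that noise
  comparable to the agreement being measured;
- concordance: organ pairs sharing 50% vs 0% of 500 planted same-sign
  effects at 200 cells/group, 2,000 genes.

Numerical conventions: all removal/inclusion thresholds are strict
inequalities as defined above; restoration ties use a `1e-12` tolerance and
resolve to persistent; undefined quantities (empty directions, zero-cell
clusters, <3-gene correlations) are reported as `NA`, never silently
filled; annotation ties resolve to the first panel in panel order with a
flag. All randomness — generation, subsampling, the pipeline — flows
through explicit integer seeds, and `run_pipeline()` is byte-deterministic
given config + seed.

## Limitations

- Restoration is binary by design; no continuous restoration score or
  longitudinal mixed model is fitted.
- Annotation is marker-mean argmax (optionally cluster-voted), not
  graph-based clustering; accuracy depends on marker enrichment.
- The GWAS join is symbol-based; no LD-aware SNP-to-gene assignment,
  EFO ontology resolution, or colocalization.
- DE is two-group Wilcoxon only — no covariate adjustment or pseudobulk
  aggregation across animals, so animal-level pseudoreplication is not
  modeled (the simulator plants no animal effects either).
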