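---
title: "Methods: lesion-centric gradient screening, mapping and signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion-centric gradient screening, mapping and signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionscape)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the parameters that matter (with units and defaults),
what the synthetic-data generators emulate and what they do not, and the
numerical choices made where the design was genuinely open. It states no
empirical result that the test suite does not itself compute.

## 1. The analysis problem

A focal cortical lesion organises the surrounding tissue radially: reactive
astrocytes, microglia and oligodendrocyte-lineage cells form a border around
the injury core, and transcriptional programs vary with distance from it.
Spot-based spatial transcriptomics captures this at 1–10 cells per spot;
droplet single-cell RNA-seq of the same tissue resolves which populations
drive each spatial signal. The package implements the corresponding
analysis chain: radial gradient screening around an annotated core,
preprocessing and clustering for both modalities, marker and condition
statistics, exclusive-intersection signature derivation, and probabilistic
cell-to-spot mapping with deconvolution.

## 2. Concentric binning and template screening

**Geometry.** All geometry is in micrometers; pixel coordinates are scaled
at read time (`read_spot_positions(um_per_px = ...)`). A lesion is a circle
(centre, radius `r0`) or a simple polygon. The boundary distance `d(s)` of a
spot is 0 inside the annotation and the Euclidean distance to the boundary
outside. Ring `k ≥ 1` holds spots with `d ∈ ((k−1)·w, k·w]` — the upper
edge is inclusive, enforced exactly against floating-point edge effects —
and bin 0 is the annotation interior. Spots beyond `B·w` or in excluded
(e.g. non-cortical) clusters are unassigned. Defaults `w = 95` µm and
`B = 13` cover ~1.2 mm; the innermost ~500 µm is the perilesional zone where
reactive gliosis concentrates.

**Templates.** The eight template models are evaluated at ring centres
`x_k = (k − ½)/B`. The named model families only specify shapes
qualitatively; the functional forms here are this package's
concretisation: `linear` `1 − x`; `immediate` `(1 − x)⁴` (core-confined);
`late` `1 − x⁴` (plateau, late drop); `abrupt` a logistic
`1/(1 + exp((x − 0.5)/0.05))` (step at mid-range, slope 0.05 chosen so the
transition spans roughly one ring). Ascending mirrors are `1 − f`. Powers
and slope are fixed, not tuned: they were chosen once to give four visually
distinct monotone archetypes.

**Screening statistic.** Profiles are ring means of log-normalised
expression (gene sets: per-spot mean over members first), min–max scaled.
Scaling does not change Pearson correlations — it standardises reporting
only. Bin 0 is excluded from the correlation by default: the screen
characterises the gradient from the core boundary outward, and the core
interior (necrotic/dense tissue) is reserved. The p-value is one-sided for
`r > 0` via `t = r√((B−2)/(1−r²))`, `df = B − 2`, because each template
already encodes its direction. Genes enter only with raw totals strictly
above 50 counts; gene sets are exempt (their members were already filtered
when the matrix was). With several lesions, profiles are averaged bin-wise,
and per-model correlations and p-values are averaged; ranking uses the mean
p-value of the winning (argmax mean-r) model, ties in the argmax broken
alphabetically. Per-model averaging (rather than averaging only the winner's
p) was an open choice; it keeps the merged table complete for every model.

**Calibration caveat.** The best model is an argmax over eight correlated
templates, so the nominal p-value of the *winning* model is anti-conservative
under the null; ranking by `p_value_mean` is unaffected, but the absolute
rates should not be read as FDR. A Benjamini–Hochberg column over
`p_value_mean` is emitted for convenience. No multiple-testing correction is
applied to the ranking itself, mirroring standard practice for this screen.

## 3. Preprocessing

- **QC** (`qc_filter`): inclusive bounds — "at least" means `≥`, "maximum"
  means `≤`. Spatial default: ≥ 1500 reads, ≤ 45% mitochondrial fraction.
  Single-cell usage: ≥ 1000 genes, ≤ 50,000 reads, ≤ 25% mitochondrial.
  Mitochondrial genes are identified by symbol prefix (default `mt-`),
  configurable because no fixed gene list is assumed.
- **Normalisation** (`normalize_log_cpm`): every observation scaled to sum
  exactly 10,000 (counts-per-N), then natural `log1p`.
- **HVGs** (`select_hvg`): dispersion = variance/mean of de-logged values;
  20 equal-frequency mean-expression bins; robust z-score (median/MAD)
  within bins; top-n (default 2000), ties alphabetical. This concretises the
  "Cell Ranger flavor", which is named but not specified to this level
  anywhere authoritative.
- **Clustering** (`cluster_graph`): per-gene z-scores clipped at |z| = 10,
  PCA (default 50 components), kNN graph (default k = 15), Leiden modularity
  at resolution 1.0, seeded. Labels are relabelled contiguous from 0,
  largest community first. The cluster count at a given resolution is data-
  and graph-dependent; no specific cluster count is claimed by default.
- **Batch centering** (`batch_center`): per batch and gene, subtract the
  batch mean and add the global mean — an intentionally linear stand-in for
  deep generative integration, which is out of scope. It removes location
  shifts only; variance and nonlinear batch structure remain.
- **Gene-set scores** (`score_gene_set`): 25 expression bins, 50 control
  genes per target gene, sampled without replacement from the target's bin
  (set members excluded from the pool); score = mean(target) −
  mean(control pool). The score of a *fixed* random set is not exactly
  zero-mean — it carries the gene-sampling noise of that one draw — so null
  calibration is asserted as a label-permutation contrast (two random
  observation groups differ by 0 within 3 SE), which is the property the
  score actually promises.

## 4. Marker and condition statistics

The marker test is the overestimated-variance t: with group mean `m_g`,
variance `s_g²`, size `n_g`, and rest mean/variance `m_r`, `s_r²`,

> `t = (m_g − m_r) / √(s_g²/n_g + s_r²/n_g)`

— the rest variance is divided by the group's own size. For a marker screen
(small cluster vs large rest) this inflates the SE and is conservative;
`|t| ≤ |t_Welch|` whenever `n_rest ≥ n_g`. Degrees of freedom follow
Welch–Satterthwaite under the same substitution. Fully degenerate genes
(zero variance in both groups, equal means) get `t = 0, p = 1` rather than
NaN. Fold changes de-log the means: `log2((e^m − 1 + ε)/(e^m' − 1 + ε))`,
`ε = 1e−9`. Testing is refused for groups below 10 observations by default
(configurable): tiny subclusters give unstable statistics.

The condition contrast is a two-group Wald z on log-normalised values with a
normal two-sided p. This deliberately replaces a count-model (negative
binomial GLM) Wald test; with the log-normalised values and group sizes used
here the normal approximation is adequate (type-I error within 0.05 ± 0.015
on null simulations, asserted in the acceptance suite), but exact parity
with count-model implementations is not claimed.

Threshold filters use the raw p-value (`pval < 0.05`, strict) and strict
log2FC bounds (e.g. `> 1.6`), matching how such cutoffs are conventionally
stated; an adjusted-p switch exists. Exclusive intersections classify every
member of the union by its exact membership signature, so subset sizes
partition the union (the UpSet convention); plain ("inclusive")
intersections are emitted alongside, because "common to these three sets"
can be read either way. Over-representation is the hypergeometric upper
tail `P(X ≥ k)` with BH across sets against a user-supplied universe and
gene sets (no ontology handling). Cluster similarity is the Jaccard index
of top-20 marker lists.

**Shared-signature derivation.** The signature shared by reactive glia is
obtained within cell types: for each glial type, subcluster its cells,
identify the injury-restricted (reactive) subcluster, rank its markers
against the same type's other subclusters, filter (`p < 0.05`,
`log2fc > 1.6`, up), and take the exclusive three-way intersection of the
astrocyte, microglia and OPC lists. Testing within the type matters:
against *all* cells the other two reactive populations sit in the rest
group and dilute the very fold changes the filter needs (measured on the
synthetic world: within-type testing recovers ≥ 90% of a planted shared
program; against-all testing recovers ~28%).

## 5. Cell-to-spot mapping and deconvolution

`fit_mapping` learns `M` (cells × spots, rows on the simplex via row
softmax) by full-batch gradient ascent on the summed per-gene cosine
between spatial expression and its prediction `MᵀS`, over a training panel
(union of top cluster markers present in the spatial data, default 20 per
cluster). Density priors and regularisers of heavier mapping tools are
deliberately omitted; the probabilistic map itself is the product. Design
choices:

- Both matrices log-normalised; each training gene unit-L2-normalised
  across cells/spots, so every gene contributes equally to the objective.
- Logits are initialised from the (deterministic) cell–spot cosine
  similarity scaled to 0.01, plus seeded noise of sd 1e−9 as a tie-break.
  Pure noise initialisation is amplified by the winner-take-all dynamics
  and would break the contract that identical cells end with identical
  rows; the similarity initialisation preserves that symmetry exactly.
- Fixed learning rate 0.1, 1000 iterations; a step that would decrease the
  objective is rejected and the rate halved, then regrown by 5% per
  accepted step (capped at 100× the initial rate). The objective is
  therefore non-decreasing by construction, and the regrowth lets the
  default budget actually converge on e.g. a 200-cell permutation fixture.
- The panel size matters for composition recovery: ~20 markers per cluster
  suffices to localise clusters, but deconvolving compositions on few
  clusters benefits from a deeper panel (the acceptance test uses 50 per
  cluster, the desk-scale analogue of a ~440-gene panel over a 30-cluster
  atlas).

`deconvolve` turns `M` into hard assignments under per-spot nuclei counts
(an input — image segmentation is out of scope): repeatedly take the
globally largest `M[i, s]` over unassigned cells and unfilled spots, ties
by cell id then spot id. Each cell is used at most once; each spot receives
exactly its nuclei count. `cluster_spot_probability` and
`radial_cluster_profiles` aggregate `M` per cluster and per ring; cluster
rows are ordered by average-linkage hierarchical clustering on correlation
distance so that co-localised populations sit together.

## 6. The synthetic world

`simulate_spatial` emulates a Visium-like section: a 40 × 40 square lattice
at 100 µm pitch (hexagonal option), a circular core of radius 200 µm at the
centre, 1–10 cells per spot, log-normal library factors (sd 0.15), and
negative binomial counts (per-cell dispersion θ = 10; a spot is the sum of
its cells' draws, which is again NB with scaled mean and size — this is
what makes deconvolution truth well defined). A planted gene with template
`f` has per-cell mean `µ·(1 + a·f(x))` with amplitude `a = 2` by default,
where `x = clamp(d/(B·w), 0, 1)` uses the screen's own geometry so
simulator and screen agree about "normalised distance". Baseline means are
log-normal (meanlog `log 5`, sdlog 1).

The default transcriptome is 4000 genes with 100 planted genes per
descending template (10% of genes in total). The planted minority is a
modelling requirement, not a tuning knob: depth normalisation couples genes
compositionally, and a world where most genes are strongly induced at the
core imprints an artificial ascending gradient on every flat gene. Real
lesion data has a few hundred gradient genes among ~15–20k measured; 10% is
already a conservative (harder) version of that ratio. A residual
compositional inflation of the null remains at 10% and is part of why the
winning-model p-values should not be read as calibrated (Section 2).

`simulate_scrna` emulates the injured-cortex single-cell design: cell types
(default astrocytes, microglia, OPCs, neurons) × states (homeostatic
everywhere; reactive only in the injured condition, glial types only) ×
conditions × batches, 100 cells per combination. Disjoint planted programs:
a 50-gene shared inflammatory program (log2FC 2 in all reactive cells), a
40-gene reactivity program per glial type (log2FC 2), a 30-gene
proliferation program expressed by a random 30% of reactive cells, and
50 identity markers per type (log2FC 3). Batch effects are per-(batch,
gene) multiplicative log-normal factors (sdlog 0.1, first batch reference).
Counts are NB (θ = 2) with log-normal cell library factors (sd 0.2).
Baseline means log-normal (meanlog `log 0.5`, sdlog 1.2), i.e. ~1–2k counts
per cell over 2000 genes.

`simulate_mixture` samples cells without replacement into 1–10-cell spots
and sums their counts, recording assignment, nuclei counts and composition
fractions — the ground truth for mapping/deconvolution recovery.

**What the generators do not emulate** — and hence what a green test does
not establish: spatial autocorrelation beyond the planted radial structure,
irregular lesion shapes, tissue-wide anatomical domains, ambient RNA,
doublets, zero-inflation beyond NB, nonlinear batch effects, and any
imaging component. Recovery rates on this world are upper bounds for real
tissue.

## 7. Numerical and degenerate-input conventions

- Identical seed and configuration give bit-identical simulator output and
  byte-identical CLI tables (stable radix sorts on declared keys; non-finite
  values serialised as `NA`).
- Constant profiles are flagged and excluded from screening with a warning;
  empty rings make a profile "incomplete" (excluded) and empty bins in
  radial cluster profiles produce flagged `NA` columns.
- Zero-total observations fail normalisation loudly, by name. All-zero
  training genes are dropped from mapping with a warning; mapping fails
  only when none remain.
- Correlation p-values are clamped to `(0, 1]`; `r = ±1` is handled by
  flooring `1 − r²` at machine epsilon.
- QC, filtering and downsampling never renumber or reorder surviving
  observations; downsampling preserves the original column order.
- The flat `key: value` config reader supports exactly one nesting level of
  nothing: scalar keys only. This is a documented limitation.

## 8. Known limitations

- The Wald contrast is a normal approximation on log-normalised values, not
  a count GLM; DEG lists from count-model tools will differ in the tails.
- The screening statistic is a faithful reading of "correlation with
  pre-defined gradient models"; other implementations of the same idea may
  smooth profiles or use different significance machinery, so numerical
  parity with them is not claimed.
- The greedy deconvolution is a deterministic assignment heuristic; it does
  not optimise a global objective.
- Polygon lesions assume simple (non-self-intersecting) geometry; distances
  are exact for circles and vertex-segment distances for polygons.
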