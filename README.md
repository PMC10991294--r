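# lesionscape

Focal brain injuries — stab wounds, and penetrating lesions generally —
reorganise the surrounding cortex into concentric zones of reactive glia and
infiltrating immune cells. `lesionscape` is an R toolkit for quantifying that
organisation from spatial transcriptomics (Visium-style spot arrays) together
with single-cell RNA-seq of the same tissue. It is aimed at analysts who have
a lesion-bearing section, an annotated injury core, and matched single-cell
data, and who want reproducible, tested primitives rather than a notebook of
one-off scripts.

## What it computes

**Radial gradient screening.** Spots are binned into `B` concentric rings of
width `w` around the annotated lesion core (defaults `B = 13`, `w = 95` µm,
covering ~1.2 mm of perilesional tissue; ring `k` holds boundary distances
`d ∈ ((k−1)w, kw]`). For each gene (or gene set) the ring-mean expression
profile `ȳ_k` is min–max scaled and correlated against eight template models
on the normalised distance `x ∈ [0, 1]`:

- `linear_descending` `f = 1 − x`, `immediate_descending` `f = (1 − x)⁴`,
  `late_descending` `f = 1 − x⁴`, `abrupt_descending` a logistic drop at
  `x = 0.5`, plus the four ascending mirrors `1 − f`.

The one-sided p-value for `r > 0` comes from
`t = r·√((B−2)/(1−r²))` on `B − 2` degrees of freedom; genes need more than
50 raw counts to enter the screen, multiple lesions are merged by bin-wise
profile means and the per-model mean p-value (`p_value_mean`), which also
ranks the output.

**Modality preprocessing.** Inclusive QC bounds (reads, genes detected,
mitochondrial fraction), counts-per-N depth normalisation with `log1p`
(target 10,000), binned-dispersion highly variable genes, Leiden graph
clustering on PCA + kNN, per-batch linear centering, group downsampling, and
control-matched gene-set scoring (score = mean(target) − mean(matched
controls)).

**Marker and condition statistics.** Cluster markers use the
overestimated-variance t test,
`t = (m_g − m_r) / √(s_g²/n_g + s_r²/n_g)` — the rest-group variance is
divided by the *group* size, deliberately inflating the SE; condition
contrasts use a two-group Wald z on log-normalised values. Fold changes are
`log2((e^m − 1 + ε) / (e^m' − 1 + ε))`. Threshold filters (`pval < 0.05`,
`|log2fc| > 1.6`, strict) feed exclusive set intersections (UpSet-style
membership signatures) — the route by which a shared inflammatory signature
common to reactive astrocytes, microglia and OPCs is derived — plus
hypergeometric over-representation and top-20-marker Jaccard similarity
matrices.

**Cell-to-spot mapping.** A row-stochastic cells × spots matrix `M`
(softmax-parameterised) is fitted by monotone gradient ascent on
`L = Σ_g cos(G[,g], MᵀS[,g])` over a training-gene panel (union of top
cluster markers detected in the spatial data). `M` yields per-cluster
spatial probabilities, radial cluster-abundance profiles, and — given
per-spot nuclei counts — a greedy hard deconvolution into per-spot cluster
compositions.

**Synthetic data.** Seeded negative-binomial generators for both modalities
with full ground truth: a lattice section with a circular lesion core and
planted template gradients (1–10 cells per spot), an injured-cortex
single-cell experiment with reactive glial states sharing a planted
inflammatory program, and a cell-mixture builder for deconvolution truth.
Every statistical claim in the test suite is exercised against these
generators or against closed-form oracles.

## Worked example

```r
library(lesionscape)

sim    <- simulate_spatial(spatial_sim_config(seed = 1))   # 4000 genes, 1600 spots
lesion <- lesion_annotation("injury1", center = sim$truth$lesion$center,
                            radius_um = sim$truth$lesion$radius_um)
bins   <- assign_concentric_bins(sim$spots, lesion, binwidth_um = 95, n_bins = 13)
norm   <- normalize_log_cpm(sim$counts)
res    <- merge_lesions(list(screen_profiles(
  compute_profiles(norm, bins), build_templates(13), min_total_counts = 50,
  raw_totals = Matrix::rowSums(sim$counts$values))))
head(res[, c("feature", "best_model", "r", "p_value_mean", "padj")])
#>    feature           best_model         r p_value_mean         padj
#> 1 gene0147 immediate_descending 0.9982806 3.304691e-15 1.321876e-11
#> 2 gene0244    abrupt_descending 0.9977761 1.359312e-14 2.398351e-11
#> 3 gene0177 immediate_descending 0.9976598 1.798763e-14 2.398351e-11
#> 4 gene0197 immediate_descending 0.9975090 2.535122e-14 2.535122e-11
#> 5 gene0270    abrupt_descending 0.9973579 3.503981e-14 2.803185e-11
#> 6 gene0216    abrupt_descending 0.9970695 6.191285e-14 3.847238e-11
```

Each row is one gene: `best_model` is the template whose shape its radial
profile matches best (`r` is the Pearson correlation over the 13 rings), and
`p_value_mean` ranks how confidently the gene follows a lesion-centric
gradient. On this seed, 99.2% of the 400 planted gradient genes are assigned
their true template. The same screen accepts GMT gene sets via the
`features` argument of `compute_profiles()`.

A command-line interface wrapping the same functions lives in
`inst/cli/lesionscape` (`simulate`, `qc`, `normalize`, `hvg`, `cluster`,
`score`, `gradient screen`, `map`, `deconvolve`, `markers`, `contrast`,
`intersect`, `enrich`, `similarity`); all seeded subcommands are
byte-reproducible.

## Further reading

The methods vignette (`vignettes/lesionscape.Rmd`) documents the model
assumptions, parameter defaults and units, what the simulators do and do not
emulate, and the numerical design choices.
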