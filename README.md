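# cellprox

Differential cell-type proximity analysis for imaging-based spatial
transcriptomics (MERFISH-style data).

After segmentation and annotation, a MERFISH experiment is a table of
cells — micrometer coordinates, physical volume, type labels, sample and
condition — plus a cell-by-gene counts matrix. `cellprox` asks whether
the *local composition of cellular neighborhoods* differs between two
conditions (e.g., normoxia- vs hypoxia-reared mice, three animals each),
and provides the standard companion analyses. It is aimed at analysts
working with segmented imaging-based spatial data who need
replicate-aware inference rather than per-cell p-values.

## What it computes

**B-ratio.** For center cell *i* and surround type *B*, with neighbor
counts inside radius *r* (closed ball, self excluded, within one sample
and region):

```
B_ratio = N_B / N_total
```

The radius is data-derived per sample and region: *d* is the median
nearest-neighbor distance ("minimum distance unit") and *r* = 5·*d*.
B-ratio is asymmetric: astrocytes around neurons is not neurons around
astrocytes.

**Differential proximity.** Per region and ordered type pair, a
Gaussian linear mixed model on the transformed response,

```
log(B_ratio + 0.001) ~ condition + (1 | sample)
```

fit by REML, Wald t test with Satterthwaite degrees of freedom for the
condition coefficient, Benjamini–Hochberg FDR within region. β > 0
means the surround type is locally more abundant near the center type
under treatment. The random intercept is what makes thousands of
per-cell observations from six tissue sections statistically honest; a
naive per-cell t test on the same data has a type-I error above 0.5 in
our null experiments (`fit_pair_naive()` exists to demonstrate this).

**Also included:** the five-stage cell-level QC cascade (volume filter,
zero-count removal, volume normalization ×1000, 2%/98% total-count
quantile filter, doublet-score > 0.20 exclusion, all strict
inequalities); cell-type proportion tests (pooled-variance Student's t
across replicates); gene-set cell-state scores (mean gene-wise z-score
per cell, replicate-level inference, four bundled signatures); and a
synthetic-tissue generator with Monte-Carlo ground truth
(`simulate_tissue()`, `empirical_ground_truth()`).

## Worked example

Simulate a two-condition tissue with a known injected attraction (42%
of astrocytes placed near OPCs in the treatment arm only), run QC, and
fit differential proximity:

```r
library(cellprox)
library(dplyr)

sim <- simulate_tissue(recovery_benchmark_config(), seed = 2)
qc  <- run_qc(sim$cells, sim$counts)
qc$report
#>                   stage  n_in n_removed n_out
#> 1                volume 26933        88 26845
#> 2           zero_counts 26845         0 26845
#> 3  volume_normalization 26845         0 26845
#> 4 total_count_quantiles 26845      1080 25765
#> 5         doublet_score 25765       738 25027

fit <- run_differential_proximity(qc$cells, type_level = "cell_type")
fit
#> <diff_prox> 9 ordered type pairs across 1 region(s); 5 significant at FDR < 0.05
#> model: log(b_ratio + 0.001) ~ condition + (1 | sample_id), REML, Wald t, Satterthwaite df

fit$distance_units |> head(2)
#>   sample_id     region     d     r multiplier n_cells
#> 1      ref1 sim_region 10.96 54.78          5    4124
#> 2      ref2 sim_region 10.80 54.01          5    4230

tidy(fit) |> arrange(fdr) |> head(4)
#>   center_type surround_type    beta      se      df        p      fdr       status
#> 1       Astro        Neuron -0.0394 0.00597 2420.00 5.02e-11 4.51e-10 singular_fit
#> 2         OPC         Astro  0.4180 0.08350 2050.00 6.19e-07 1.86e-06 singular_fit
#> 3         OPC        Neuron -0.0452 0.00903 2050.00 6.07e-07 1.86e-06 singular_fit
#> 4       Astro           OPC  0.5550 0.09850    4.18 4.28e-03 9.64e-03           ok
```

Reading the table: the injected OPC → Astro pair is recovered with
β = 0.42 (astrocytes make up e^0.42 ≈ 1.5× higher a share of OPC
neighborhoods under treatment). The reciprocal Astro → OPC pair is also
significant — placing astrocytes near OPCs necessarily puts OPCs near
those astrocytes (pair counts are symmetric; see the vignette) — and
the Neuron pairs show the compensating depletion of the majority type.
`autoplot(fit)` draws the per-region β heatmap with significance marks;
`beta_matrix(fit)` exports the matrices.

For real data, start from `read_cell_table("cells.csv")` and
`read_counts("counts.csv")` (CSV/TSV or MatrixMarket with name
sidecars), with configurable column and condition mappings.

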