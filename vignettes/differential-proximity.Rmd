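---
title: "Differential cell-type proximity from imaging-based spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential cell-type proximity from imaging-based spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellprox)
library(dplyr)
```

## The problem

Imaging-based spatial transcriptomics (MERFISH and kin) yields, after
segmentation and annotation, a table of cells with micrometer-scale
centroids, physical volumes, type labels, and a cell-by-gene counts
matrix. Given such tables from two experimental conditions — for
example brains of mouse pups reared in normoxia (the reference) versus
chronic sublethal hypoxia (the treatment), three animals each — the
question is whether the *local composition of cellular neighborhoods*
changes: does one cell type become more or less locally abundant around
another under the treatment?

`cellprox` implements a complete pipeline for that question: cell-level
quality control, a local-composition statistic with a data-derived
radius, mixed-effects differential testing, plus the two companion
analyses usually reported alongside (cell-type proportion tests and
gene-set cell-state scores), and a synthetic-tissue generator with
known ground truth that validates every stage.

## The B-ratio statistic

For a center cell $i$ and a surround type $B$, count the other cells of
the same sample and region within Euclidean distance $r$ of $i$: the
total $N_{\mathrm{total}}$ and the number of type-$B$ cells $N_B$. The
local proportion

$$B_{\mathrm{ratio}} = N_B / N_{\mathrm{total}}$$

is an asymmetric statistic: the proportion of astrocytes around neurons
is not the proportion of neurons around astrocytes. Cells with
$N_{\mathrm{total}} = 0$ contribute no observation (0/0 is undefined);
they are tallied in a skipped-cells report.

The radius is derived from the data, per sample and region: $d$ is the
median over cells of each cell's nearest-neighbor distance (the
"minimum distance unit" — roughly one cell diameter at typical
packing), and $r = 5d$, restricting the neighborhood to immediate
proximity. Two conventions are deliberate and declared: the
neighborhood is a *closed* ball (distance exactly $r$ is inside), and a
cell is never its own neighbor. Neighbor search uses a k-d tree
(`RANN`); strata never mix samples or regions.

## The differential model

Per region and ordered type pair $(A, B)$, the condition effect is
estimated by a Gaussian linear mixed model on the transformed response

$$\log(B_{\mathrm{ratio}} + 0.001) \sim \textrm{condition} + (1 \mid \textrm{sample}),$$

fit by REML. The 0.001 offset keeps zero ratios finite; the log is
natural, so effects are interpretable as log fold-changes of the local
proportion. The random intercept absorbs sample-to-sample shifts, which
is what makes per-cell observations usable at all: cells from one
tissue section are not independent, and a model ignoring that is badly
anticonservative (the package ships `fit_pair_naive()` purely to
demonstrate this; on null tissues with realistic sample effects its
type-I error is above 0.5 while the mixed model sits near 0.05).

Design choices that were genuinely open:

* **p-values.** The condition coefficient is tested with a Wald $t$
  statistic using Satterthwaite denominator degrees of freedom
  (`lmerTest`). With three samples per arm the effective degrees of
  freedom are about four; a normal-reference Wald test is
  anticonservative at that size (empirically about 0.10 type-I at
  nominal 0.05), while the Satterthwaite test calibrates within
  [0.02, 0.09] in our null experiments.
* **Singular fits.** When the REML estimate of the random-intercept
  variance lands exactly on the zero boundary, the pair is refit
  without the random intercept and flagged `singular_fit`. These fits
  carry valid p-values and stay in the FDR family; pairs with too
  little data (fewer than 2 samples or 10 center cells per condition,
  or no response variance) are flagged `insufficient_data`, excluded
  from the family, and shown as gray cells in the matrix export.
* **FDR family.** Benjamini–Hochberg within region across all ordered
  pairs that produced a p-value, matching the per-region heatmap
  layout in which results are read.
* **Sign convention.** Condition labels are normalized at import
  (default NX → reference, HX → treatment), and $\beta > 0$ always
  means the surround type is locally more abundant near the center type
  in the treatment.

## The QC cascade

Five stages, in a fixed order, all thresholds strict (boundary cells
are kept):

1. volume filter: drop cells with volume `< 50` µm³ or `> 3×` the
   median volume of all input cells;
2. drop cells with zero total counts;
3. volume-normalize: counts / volume × 1000 (compensates partial soma
   capture in a thin section);
4. drop cells whose normalized totals fall strictly outside the
   [2%, 98%] type-7 empirical quantile band — computed per sample by
   default, since each sample is a separate tissue run (a pooled option
   exists);
5. drop cells with doublet score `> 0.20`; unscored cells pass and are
   counted separately (score computation is upstream of this package).

The report telescopes (each stage's survivors are the next stage's
input), and the order matters: the volume median, the quantile band and
the normalized totals all depend on which cells are still present. A
designed 12-cell fixture (`simulate_qc_fixture()`) trips each rule
exactly once and pins the expected 8 survivors, including the three
boundary cells.

## Proportions and state scores

`compute_proportions()` divides subtype counts by the region total or
by the broad-class total, per sample and region.
`proportion_ttest()` is the unpaired two-tailed pooled-variance
Student's t comparing the three reference to the three treatment
replicate proportions; percent change is relative to the reference
mean.

State scores z-score each signature gene across all cells in the
scoring scope (conditions pooled, sample standard deviation, ddof = 1;
zero-variance genes contribute 0) and average over the signature; the
scores are therefore centered at zero over the scope by construction.
Four signatures ship with the package (OL genesis, OL maturation,
reactive astrocyte, reactive microglia); the curated reactive-microglia
list contains one duplicated symbol (*Cst7*), stored once, and the
astrocyte list's lowercase "lcn2" is resolved by a case-insensitive
fallback that is on by default and logged. Inference is replicate
level: scores are averaged within (sample, region, cell group) and the
t test runs across replicate means, so its n is the number of animals,
never the number of cells — multiplying cells per replicate tenfold
with replicate means held fixed leaves the p-value unchanged, and a
regression test asserts exactly that.

## The synthetic-tissue generator

`simulate_tissue()` draws, per sample, a homogeneous Poisson number of
cells placed uniformly on a rectangle, types them by per-sample
proportions, and adds log-normal volumes (median ≈ 180 µm³), doublet
flags with scores, and negative-binomial counts with type-marker
structure (≈ 285 transcripts/cell) — the magnitudes echo typical
MERFISH summaries as realism anchors only.

Two mechanisms deserve explanation because their design was the least
obvious part of the package:

* **Sample-level random effects** cannot be imposed as an additive
  intercept on $\log(B_{\mathrm{ratio}})$ of a point process. They are
  induced generatively: per-sample log-normal jitter (sd
  `sample_effect_sd`) multiplies the type proportions (and any
  attraction placement fraction). The *realized* between-sample sd on
  the log-ratio scale is larger than the nominal knob — the zero
  fraction amplifies composition jitter — so it is estimated by
  simulation and reported rather than assumed.
* **Attraction** between a center type A and satellite type B places a
  fraction $f$ of B cells within a placement radius of an A cell by
  *label exchange*: non-A, non-B cells inside the A-disks become B,
  and an equal number of B cells elsewhere take their labels. Positions
  are untouched, so both conditions share an identical point pattern in
  law — the distance unit $d$, local densities and all denominators are
  condition-independent, and only the local type composition carries
  the effect. (The naive alternative, physically relocating B cells,
  clumps the treatment pattern: $d$ shrinks, denominators inflate, and
  the measured effect on the mean log ratio can even flip sign.)

`empirical_ground_truth()` estimates, by Monte-Carlo over replicate
tissues, the expected condition difference in mean
$\log(B_{\mathrm{ratio}} + 0.001)$ for every ordered pair under a
configuration — the recovery target for the differential model.

### What the generator shows, and a structural limitation

Two frozen designs drive the validation suite. The *null benchmark*
(three types 40/35/25%, ≈ 2,000 cells per 1 × 1 mm sample, 3 + 3
samples, proportion jitter sd 0.1) checks calibration: across 200
simulated tissues the mixed model's per-pair type-I error at α = 0.05
must lie in [0.02, 0.09] while the naive per-cell t test fails that
bound spectacularly. The *recovery benchmark* (Neuron 82%, Astro 10%,
OPC 8%, 1.5 × 1.5 mm, ≈ 4,500 cells and ≥ 350 OPC centers per sample,
f = 0.42, placement radius 1.5 × the expected nearest-neighbor
distance) was calibrated by `empirical_ground_truth()` so the injected
OPC → Astro difference is ≈ 0.5 log units; sizes were set by a
design-time power analysis against the measured per-cell variance.

One limitation is worth stating plainly because it is a property of
*any* generator of this kind, not of the implementation. The number of
(A, B) pairs within radius $r$ is a single symmetric quantity: "more B
near A" is arithmetically "more A near B". Any mechanism that brings B
cells close to A cells therefore moves *both* ordered mean ratios by
the same first-order relative amount, and the satellite cells' own view
(B → A) typically moves *more*, because each placed satellite is
guaranteed a center-type neighbor while the centers share the incoming
satellites. The asymmetry of $B_{\mathrm{ratio}}$ is an asymmetry of
*levels* (satellites surrounded almost entirely by A while A cells see
few B — reproduced exactly by the test suite), not of differential
effects. Consequently a simulated one-directional attraction produces
significant effects in both ordered directions, and detection of the
reverse pair should be expected; analyses of real tissue should read
the two directions of a significant pair together rather than as
independent findings. Relatedly, detecting a 0.5 log-unit shift with
three replicates per arm at FDR < 0.05 has moderate power (about
60–70% in our experiments): per-cell log ratios are extremely variable
(zero neighborhoods sit at $\log 0.001 \approx -6.9$), and with six
samples the Wald t has about four denominator degrees of freedom.

## Numerical conventions

* Quantiles: type-7 (linear interpolation), declared in the QC report.
* Logarithms: natural, everywhere.
* Ball boundary: closed (`distance <= r`).
* Ties and zeros: zero-variance genes contribute 0 to scores;
  zero-variance t tests return p = 1 (equal means) or p = 0 with a
  warning (unequal means).
* All simulations take explicit seeds; the same seed gives
  byte-identical tissues, and the caller's RNG state is preserved.
* Problem sizes in the shipped validation suite: 20 oracle tissues of
  100–500 cells; 200 null tissues (≈ 12,000 cells each); 50 recovery
  tissues (≈ 27,000 cells each); 100 exact-model coverage simulations.

## A worked example

```{r example, eval = FALSE}
library(cellprox)

cfg <- recovery_benchmark_config()
sim <- simulate_tissue(cfg, seed = 1)

qc <- run_qc(sim$cells, sim$counts)
qc$report

fit <- run_differential_proximity(qc$cells, type_level = "cell_type")
tidy(fit) |> dplyr::arrange(fdr)
autoplot(fit)

test_proportions(qc$cells)

# bundled signatures (state_score_genes("ol_genesis"), ...) apply to real
# gene panels; the synthetic panel uses its own gene names
sc <- compute_state_score(qc$counts, c("shared_1", "shared_2", "shared_3"))
score_group_means_and_test(sc, qc$cells)$tests
```

The README shows this example with the numbers it printed.

## Known limitations

* Two-dimensional geometry only: the thin section is collapsed; no 3-D
  neighbor search.
* The generator does not emulate segmentation errors, spatially varying
  density gradients, transcriptome-wide counts, or region anatomy; a
  passing suite shows the statistics behave as designed under the
  stated generative model, not that any particular biological claim
  holds on real tissue.
* Edge effects: cells near the tissue border have truncated
  neighborhoods. `trim_boundary()` lets analyses drop a margin of
  width $r$; the shipped benchmarks keep edge cells, as whole-tissue
  analyses typically do.
* No covariates beyond condition, no spatial autocorrelation between
  center cells (each center contributes an observation as if
  exchangeable within its sample), and no simulation-based residual
  diagnostics.
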