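---
title: "Methods: phasor-FLIM cytotyping of islet cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phasor-FLIM cytotyping of islet cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the scientific model, the frozen conventions, the
default parameters and the deliberate design choices behind
`isletcytotyper`. Code chunks are illustrative and not evaluated when the
vignette is built; the same computations run, with assertions, in the
package's test suite.

## The measurement model

Pancreatic islets contain glucagon-secreting alpha cells and
insulin-secreting beta cells. Both autofluoresce under infrared two-photon
excitation through two intrinsic signals:

* **NAD(P)H**, whose fluorescence lifetime depends on its binding state —
  roughly 0.4 ns free in solution versus 3.4 ns protein-bound — so the
  free/bound balance reports glycolytic versus oxidative metabolism, and
* **lipofuscin**, a bright granular lysosomal byproduct whose load is
  roughly twofold higher in beta cells.

Fluorescence-lifetime images are analysed in the **phasor** domain: the
photon-count decay $c(t)$ of each pixel maps to
$g = \sum_i c_i \cos(\omega t_i) / \sum_i c_i$,
$s = \sum_i c_i \sin(\omega t_i) / \sum_i c_i$ with
$\omega = 2\pi f_\mathrm{rep}$ ($f_\mathrm{rep} = 80$ MHz by default).
Mono-exponential decays of lifetime $\tau$ land on the universal semicircle
at $g = 1/(1+(\omega\tau)^2)$, $s = \omega\tau/(1+(\omega\tau)^2)$, and
mixtures land on photon-weighted chords between their components
(`decay_to_phasor()`, `phasor_of_lifetime()`).

Each cell is imaged at two glucose concentrations, 2.2 mM and 16.7 mM.
Glucose stimulation moves a beta cell's phasor barycenter toward the bound
pole; `metabolic_shift()` reports that displacement and its signed
projection on the free-to-bound axis.

## Feature extraction

One cell at one condition is a `cell_bundle()` — intensity image, per-pixel
(g, s) maps and a single-cell ROI mask. `extract_cell_features()` turns a
low/high-glucose bundle pair into a frozen **151-feature record**
(`feature_schema()`):

* 12 descriptive statistics (`descriptive_stats()`: min, max, mean, median,
  sd, type-7 quartiles, IQR, Tukey whiskers, 64-bin histogram mode,
  population skewness) of the intensity over all / lipofuscin / non-lipofuscin
  pixels and of the lipofuscin-excluded g and s populations, per condition;
* per-condition singletons: total photon count, phasor dispersion,
  phase/modulation lifetimes of the barycenter, bound-fraction estimate, and
  five lipofuscin descriptors from `lipofuscin_mask()` (granule area
  fraction, count, mean size, density, intensity ratio);
* the four glucose-shift descriptors, three morphology descriptors
  (`mask_morphology()`), three donor covariates, and the row's glucose
  indicator.

Lipofuscin granules are bright outliers above median + 3 MAD inside the
cell, grouped with **8-connectivity** (`label_components()`; written in the
package because the available image library labels 4-connected components
only) and kept when at least 4 px large. Phasor statistics exclude granule
pixels so the metabolic features describe NAD(P)H, not lipofuscin.

**Perimeter estimator.** `mask_morphology()` Gaussian-smooths the mask
(sigma 1.2 px) and traces the 0.5-level contour. This removes the staircase
bias of pixelated boundaries — a rasterized disk recovers circularity within
1% — at the cost of rounding sharp corners (a rasterized square scores about
0.84 instead of $\pi/4 \approx 0.785$). Cells are blob-like, so the
smoothing bias is negligible where it matters; the square anchor is asserted
analytically via `circularity()`.

Empty pixel populations (e.g. a granule-free cell) yield `NA` features;
downstream imputation maps them to 0, meaning absence of signal.

## Synthetic cohorts

`synth_config()` + `generate_cohort()` / `generate_feature_matrix()`
generate islet cohorts whose statistical structure matches the assumptions
above, so every stage is testable without microscope data. Defaults describe
the study condition the pipeline targets:

* 966 cells, two-thirds beta, from 4 donors (age 46–85, BMI 23–27.7,
  stimulatory index sampled U(1.5, 4) — a typical human-islet stimulation
  range, chosen once since no published value was available);
* star-convex cell masks (24 vertices, up to 20% radius perturbation,
  mean radius 24 px);
* lognormal base intensities (beta brighter than alpha), Poisson shot noise;
* lipofuscin granule counts Poisson with mean 2 (alpha) versus 4 (beta) —
  the configured twofold load — radius 2–4 px, 4x brightness. Granules are
  kept sparse deliberately: with larger/denser granules they merge into
  single components inside beta cells and the realised beta/alpha
  area-fraction ratio erodes well below the configured twofold, which would
  make the injected effect unrecoverable by construction;
* granule pixels decay as a 75% lipofuscin (mono-exponential 1.5 ns) / 25%
  NAD(P)H mixture — plausible values fixed once, as lipofuscin photophysics
  is not standardised;
* bound fractions at low glucose 0.30 (alpha) / 0.35 (beta), with a
  glucose-induced increase of 0.02 (alpha) versus 0.10 (beta) — the
  beta-specific metabolic shift — plus a per-cell response heterogeneity of
  s.d. 0.04. Without that heterogeneity the shift is a per-type constant and
  the classes separate perfectly (held-out AUC 1.0), which no real cohort
  shows; with it, the shift alone carries a d' of about 1.4 (single-feature
  AUC roughly 0.84) and the combined task lands in the strong-but-imperfect
  regime the pipeline is designed to assess.

Two renderers serve as mutual oracles: `method = "decay"` synthesises
per-pixel 256-bin decay histograms and Fourier-transforms them;
`method = "analytic"` draws (g, s) from the closed-form mixture phasor plus
the delta-method shot-noise Gaussian. They agree in distribution and are
cross-checked in the tests. The feature path (`generate_feature_matrix()`)
renders each cell in a tight crop, so cohorts of ~1000 cells fit easily in
memory; `generate_cohort()` keeps full-size rasters and guards against
multi-GB requests.

## Exploratory analysis

`explore_features()` imputes, min-max scales, embeds with mean-centered PCA
(`pca_embed()`, deterministic largest-loading-positive sign convention),
scans k-means over k (`elbow_scan()`, normalized WCSS
$\frac{1}{N}\sum_i \|x_i - c_{a(i)}\|^2$, knee at the maximum discrete
curvature of the axis-normalized curve — the visual elbow), and reports cluster-label purity as the unweighted mean
Gini impurity $G(j) = 1 - \sum_k (n_{kj}/n_j)^2$ plus a two-cluster ROC AUC
baseline. PCA was chosen as the embedding for the elbow input; a nonlinear
UMAP embedding is a plausible alternative but is neither deterministic nor
available here, and the clustering diagnostics do not depend on it.

## Preprocessing

`preprocess_split()` runs, in order: zero imputation, stratified split
(`round(test_fraction * n)` per class, so 861 labelled rows yield 216 test
rows at 0.25), local-outlier-factor replacement (hand-implemented Breunig
LOF, k = 20; rows with LOF > 1.5 — the usual automatic contamination rule —
are replaced by inlier column means), min-max scaling, and SMOTE
(hand-implemented: synthetic minority rows $x + u(x_{nn} - x)$, $u \sim
U(0,1)$, k = 5 minority neighbours, to exact balance). LOF and SMOTE are
implemented in the package because no equivalent is installed; both are
oracle-tested.

The outlier, scaling and SMOTE states are fitted on the **training
partition only** — splitting first avoids test-set leakage. Because a prose
description of such pipelines often implies fitting on the full matrix
before splitting, `paper_faithful = TRUE` reproduces that variant
explicitly, so the difference is measurable rather than silent.

**Row layout.** The default layout emits one row per cell per glucose
condition (two rows per cell sharing the pair-derived features, differing
in the glucose indicator). Since the two rows of a cell are near-duplicates,
a random row split would leak cells across partitions; quantitative
benchmarks in this package therefore use `layout = "per_cell"` (one row per
cell), keeping the per-condition layout available for schema-shaped
exports.

## Classification and tuning

`model_spec()` declares boosted trees (xgboost), ridge logistic regression,
RBF SVM or kNN, with compact default grids. `cross_validate()` tunes by
mean ROC AUC (beta positive) under repeated stratified k-fold CV (5 folds x
3 repeats by default), either over the whole grid or with a seeded
`sampled` strategy with median-rule pruning after the first repeat — a
budgeted stand-in for Bayesian search, which is out of scope.
`importance_ranking()` exposes normalized gain importances and
`feature_cutoff_sweep()` retunes on top-k subsets, breaking ties toward
fewer features.

## Stability battery

* `salzberg_test()` — retrain the identical pipeline on permuted training
  labels; near-chance held-out AUC certifies the real score is not leakage.
  The identity permutation reproduces the real run exactly, which the tests
  assert.
* `tenfold_variant()` — retune at 10 folds and report the difference.
* `classify_excluded()` — score records excluded by the cleaning manifest.

## Problem sizes and reproducibility

All stage seeds derive from one global seed via `derive_seed()`. Tests and
the benchmark use: tiny analytic instances (exact anchors), 30–80-cell
cohorts at 64–96 px (oracle and pipeline smoke tests), and one 900-cell
per-cell-layout cohort at 128 px for parameter recovery (held-out ROC AUC,
beta-versus-alpha precision ordering, shuffled-label control). Cohort
generation for 900 cells takes under a minute on one CPU; the tuned
boosted-tree run with the shuffled control takes a few minutes.

## Limitations

* The generator is a statistical emulator, not an optical simulation: no
  PSF, no depth-dependent scattering, no instrument response function.
* Perimeter smoothing biases sharp-cornered masks (documented above).
* The bound-fraction estimate is a chord projection, valid near the
  free/bound axis only.
* Donor covariates are sampled independently; real donor effects (age x
  lipofuscin coupling, for instance) are not modelled.
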