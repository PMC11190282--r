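# isletcytotyper

Machine-learning recognition of glucagon-secreting **alpha** cells and
insulin-secreting **beta** cells in label-free infrared micrographs of living
human islets of Langerhans.

## The science in brief

Islet cells autofluoresce without any staining through two intrinsic
signals. **NAD(P)H** changes its fluorescence lifetime with its binding
state (about 0.4 ns free versus 3.4 ns protein-bound), so lifetime imaging
reports each cell's glycolytic-versus-oxidative metabolic balance — and beta
cells respond to a glucose step (2.2 mM to 16.7 mM) with a much stronger
shift toward the bound, oxidative pole than alpha cells do. **Lipofuscin**,
a bright granular lysosomal byproduct, accumulates about twofold more in
beta cells. Neither contrast needs a label, so both are available in living
tissue.

The pipeline turns these two physiological contrasts into a classifier:

1. **Phasor transform.** Each pixel's lifetime decay maps to coordinates
   (g, s); mono-exponential decays land on the universal semicircle,
   mixtures on chords between their components (`decay_to_phasor()`).
2. **Feature extraction.** Each cell, imaged at both glucose levels, becomes
   a frozen 151-feature record (`feature_schema()`): descriptive statistics
   of intensity and of the lipofuscin-excluded phasor populations, granule
   descriptors from robust bright-outlier segmentation
   (`lipofuscin_mask()`), the glucose-induced phasor shift
   (`metabolic_shift()`), morphology and donor covariates.
3. **Exploration.** PCA, a k-means elbow scan with normalized WCSS, Gini
   cluster impurity and a two-cluster ROC AUC baseline (`explore_features()`)
   show how much structure is visible *without* labels.
4. **Preprocessing.** Zero imputation, stratified split, local-outlier-factor
   replacement, min-max scaling and SMOTE rebalancing, with every state
   fitted on the training partition only (`preprocess_split()`).
5. **Classification.** Tuned gradient-boosted trees (plus ridge logistic,
   RBF SVM and kNN baselines) under repeated stratified cross-validation
   (`cross_validate()`), with gain-importance feature selection
   (`importance_ranking()`, `feature_cutoff_sweep()`).
6. **Stability.** A label-shuffle (Salzberg) control, a ten-fold
   cross-validation variant and classification of cleaning-excluded records
   (`salzberg_test()`, `tenfold_variant()`, `classify_excluded()`).

Because the deposited micrographs are not shipped, the package includes a
**synthetic islet generator** (`synth_config()`, `generate_cohort()`,
`generate_feature_matrix()`) that reproduces the statistical structure the
analysis assumes — star-convex cells, Poisson photon noise, lognormal
intensities, the twofold lipofuscin load and the beta-specific metabolic
shift — so every stage is testable end to end. Two independent renderers
(decay-histogram synthesis and a closed-form analytic path) act as mutual
oracles.

## Worked example

```r
library(isletcytotyper)

cfg <- synth_config(n_cells = 120, image_size = 96, seed = 1,
                    layout = "per_cell")
features <- generate_feature_matrix(cfg)
features[1:4, c("cell_id", "donor_id", "cell_type", "shift_projection",
                "lipo_area_fraction_lowG")]
#> # A tibble: 4 × 5
#>   cell_id donor_id cell_type shift_projection lipo_area_fraction_lowG
#>   <chr>   <chr>    <fct>                <dbl>                   <dbl>
#> 1 C0012   D01      beta                0.0409                  0.0944
#> 2 C0024   D01      beta                0.0695                  0.0623
#> 3 C0052   D01      beta                0.0595                  0
#> 4 C0056   D01      beta                0.121                   0.0762

ex <- explore_features(features, k_max = 12, seed = 1)
c(knee = ex$elbow$knee_k, gini = round(ex$gini$mean_gini, 3),
  cluster_auc = round(ex$cluster_auc$roc_auc, 3))
#> knee k: 5  mean Gini: 0.138  cluster AUC: 0.781

prep <- preprocess_split(features, seed = 1)
fit <- cross_validate(prep$train$x, prep$train$y, model_spec("boosted_trees"),
                      cv_spec(5, 1, seed = 1),
                      search_spec("sampled", budget = 8, seed = 1))
fit
#> Tuned boosted_trees model: CV ROC AUC 0.990 over 8 trial(s)
#>   best: nrounds=60, max_depth=6, eta=0.1, min_child_weight=3

evaluate_model(fit, prep$test$x, prep$test$y)
#> Classification report (n = 30, threshold = 0.50)
#>   ROC AUC:  0.91
#>   Accuracy: 0.9
#> # A tibble: 2 × 4
#>   class precision recall    f1
#>   <chr>     <dbl>  <dbl> <dbl>
#> 1 alpha     0.889   0.8  0.842
#> 2 beta      0.905   0.95 0.927

head(importance_ranking(fit), 5)
#> # A tibble: 5 × 3
#>    rank feature              importance
#>   <int> <chr>                     <dbl>
#> 1     1 g_mean_highG             0.325
#> 2     2 g_whisker_high_highG     0.297
#> 3     3 g_q3_highG               0.224
#> 4     4 s_mode_highG             0.0696
#> 5     5 g_mode_lowG              0.0364
```

The phasor position at high glucose dominates the ranking — the
beta-specific metabolic shift is exactly the signal the generator injects.
`run_pipeline()` chains all stages (including the stability battery) from
one config and one seed, and writes a JSON summary reproducible
bit-for-bit from the same inputs. `predict_cells()` applies a trained model
plus its preprocessing state to new feature records, and
`tidy()`/`glance()`/`autoplot()`/`plot_*()` accessors cover the fitted
objects. See `vignette("methods")` for the model, the frozen conventions
and every default's rationale.

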