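test_that("synth_config computes class counts and validates parameters", {
  cfg <- synth_config()
  expect_s3_class(cfg, "synth_config")
  expect_equal(cfg$n_cells, 966L)
  expect_equal(cfg$n_beta + cfg$n_alpha, 966L)
  expect_equal(cfg$n_beta, round(966 * 2 / 3))
  cfg2 <- synth_config(n_cells = 966, beta_fraction = 654 / 966)
  expect_equal(cfg2$n_beta, 654L)
  expect_equal(cfg2$n_alpha, 312L)
  expect_error(synth_config(n_cells = 4, beta_fraction = 0.01))
  expect_error(synth_config(tau_free = 3.4, tau_bound = 0.4))
})

test_that("generate_feature_matrix is reproducible and correctly labelled", {
  cfg <- synth_config(n_cells = 10, image_size = 64, cell_radius = 12,
                      seed = 5)
  fm1 <- generate_feature_matrix(cfg)
  fm2 <- generate_feature_matrix(cfg)
  expect_equal(fm1, fm2)
  expect_equal(nrow(fm1), 20L) # per-condition layout: two rows per cell
  expect_equal(length(feature_columns(fm1)), 151L)
  counts <- table(fm1$cell_type) / 2
  expect_equal(as.integer(counts[["beta"]]), cfg$n_beta)
  expect_equal(as.integer(counts[["alpha"]]), cfg$n_alpha)
  truth <- attr(fm1, "truth")
  expect_equal(nrow(truth), 10L)
  # a different seed gives a different cohort
  fm3 <- generate_feature_matrix(synth_config(n_cells = 10, image_size = 64,
                                              cell_radius = 12, seed = 6))
  expect_false(isTRUE(all.equal(fm1$intensity_all_mean_lowG,
                                fm3$intensity_all_mean_lowG)))
})

test_that("decay and analytic renderers agree as mutual oracles", {
  cfg <- synth_config(n_cells = 30, image_size = 96, seed = 12,
                      layout = "per_cell")
  fa <- generate_feature_matrix(cfg, method = "analytic")
  fd <- generate_feature_matrix(cfg, method = "decay")
  # identical generative truth (same seed drives the same draws)
  expect_equal(attr(fa, "truth"), attr(fd, "truth"))
  expect_equal(fa$cell_type, fd$cell_type)
  # phasor population means agree within shot-noise tolerance
  for (col in c("g_mean_lowG", "s_mean_lowG", "g_mean_highG", "s_mean_highG"))
    expect_equal(mean(fa[[col]]), mean(fd[[col]]), tolerance = 0.01)
  # intensity rasters are drawn identically up to the Poisson stream
  expect_equal(mean(fa$intensity_all_mean_lowG),
               mean(fd$intensity_all_mean_lowG), tolerance = 0.05)
})

test_that("generate_cohort produces full-size bundles and guards memory", {
  co <- fx_cohort_small()
  expect_s3_class(co, "synthetic_cohort")
  expect_equal(length(co$bundles), 6L)
  b <- co$bundles[[1]]
  expect_s3_class(b$low, "cell_bundle")
  expect_equal(dim(b$low$intensity), c(64L, 64L))
  expect_equal(b$low$condition, 2.2)
  expect_equal(b$high$condition, 16.7)
  expect_equal(nrow(co$labels), 6L)
  expect_equal(nrow(co$donor_table), co$config$donor_params$n_donors)
  expect_error(generate_cohort(synth_config(n_cells = 966)), "GB")
})

test_that("generated phasors stay essentially inside the semicircle", {
  b <- fx_cohort_small()$bundles[[1]]$low
  inside <- b$roi_mask > 0
  frac_out <- mean(phasor_outside_semicircle(b$g_map[inside],
                                             b$s_map[inside], tol = 0.02))
  expect_lt(frac_out, 0.2) # shot noise scatters some pixels, not the bulk
})

test_that("the configured class differences are recovered from the images", {
  fm <- fx_fm900()
  ab <- function(col) mean(fm[[col]][fm$cell_type == "beta"]) /
    mean(fm[[col]][fm$cell_type == "alpha"])
  # twofold lipofuscin load
  expect_gt(ab("lipo_area_fraction_lowG"), 1.6)
  expect_lt(ab("lipo_area_fraction_lowG"), 2.4)
  expect_gt(ab("lipo_granule_count_lowG"), 1.4)
  # beta-specific glucose shift toward the bound pole
  proj_beta <- mean(fm$shift_projection[fm$cell_type == "beta"])
  proj_alpha <- mean(fm$shift_projection[fm$cell_type == "alpha"])
  expect_gt(proj_beta, proj_alpha + 0.02)
  # brighter beta cells
  expect_gt(ab("intensity_all_mean_lowG"), 1.1)
})

test_that("synthetic_manifest draws valid reason-coded exclusions", {
  ids <- sprintf("c%03d", 1:50)
  mf <- synthetic_manifest(ids, fraction = 0.1, seed = 3)
  expect_equal(nrow(mf), 5L)
  expect_true(all(mf$cell_id %in% ids))
  expect_true(all(mf$reason %in% c("ambiguous-identity", "rearrangement",
                                   "focal-plane-mismatch", "shape-change",
                                   "duplicate")))
  expect_equal(synthetic_manifest(ids, fraction = 0.1, seed = 3), mf)
})
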