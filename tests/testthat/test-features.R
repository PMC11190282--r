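# Hand-built bundle: disk cell, flat intensity, spatially constant phasor.
flat_bundle <- function(cell_id, condition, tau, intensity = 100) {
  mask <- fx_disk_mask(r = 8, margin = 3)
  ph <- phasor_of_lifetime(tau)
  cell_bundle(cell_id, "I1", "D01", condition,
              intensity = matrix(intensity, nrow(mask), ncol(mask)),
              g_map = matrix(ph$g, nrow(mask), ncol(mask)),
              s_map = matrix(ph$s, nrow(mask), ncol(mask)),
              roi_mask = mask)
}
flat_donor <- data.frame(age = 60, bmi = 25, si = 2.5)

test_that("cell_bundle validates shapes, mask and condition", {
  expect_error(flat_bundle("c", 5, 1), "2.2")
  m <- fx_disk_mask(r = 4, margin = 2)
  expect_error(cell_bundle("c", "I", "D", 2.2, matrix(1, 3, 3),
                           matrix(1, nrow(m), ncol(m)) * 0.5,
                           matrix(0.3, nrow(m), ncol(m)), m),
               "differ in shape")
  expect_error(cell_bundle("c", "I", "D", 2.2, m * 0, m * 0, m * 0, m * 0),
               "empty ROI mask")
})

test_that("extract_cell_features yields the exact 151-feature schema", {
  lo <- flat_bundle("c1", 2.2, tau = 1.6)
  hi <- flat_bundle("c1", 16.7, tau = 1.2)
  rec <- extract_cell_features(lo, hi, flat_donor, label = "beta")
  expect_s3_class(rec, "cell_record")
  expect_identical(names(rec$features), feature_schema()$name)
  expect_equal(length(rec$features), 151L)
  ph_lo <- phasor_of_lifetime(1.6)
  ph_hi <- phasor_of_lifetime(1.2)
  expect_equal(rec$features[["g_mean_lowG"]], ph_lo$g)
  expect_equal(rec$features[["s_mean_highG"]], ph_hi$s)
  expect_equal(rec$features[["g_sd_lowG"]], 0)
  expect_equal(rec$features[["phasor_dispersion_lowG"]], 0)
  expect_equal(rec$features[["tau_phase_lowG"]], 1.6, tolerance = 1e-10)
  expect_equal(rec$features[["tau_mod_highG"]], 1.2, tolerance = 1e-10)
  expect_equal(rec$features[["intensity_all_mean_lowG"]], 100)
  expect_equal(rec$features[["intensity_total_lowG"]],
               100 * sum(lo$roi_mask))
  # flat intensity: no granules, lipofuscin block reports absence
  expect_equal(rec$features[["lipo_granule_count_lowG"]], 0)
  expect_true(is.na(rec$features[["lipo_mean_granule_size_lowG"]]))
  # shift equals the independent metabolic_shift computation
  sh <- metabolic_shift(cloud_summary(data.frame(g = ph_lo$g, s = ph_lo$s)),
                        cloud_summary(data.frame(g = ph_hi$g, s = ph_hi$s)))
  expect_equal(rec$features[["shift_projection"]], sh$projection)
  expect_equal(rec$features[["shift_magnitude"]], sh$magnitude)
  # shortening lifetime = moving toward the free pole: negative projection
  expect_lt(rec$features[["shift_projection"]], 0)
  expect_equal(rec$features[["donor_age"]], 60)
  expect_true(is.na(rec$features[["exp_glucose"]]))
  expect_equal(rec$features[["morph_area"]], sum(lo$roi_mask))
})

test_that("extract_cell_features rejects mismatched bundle pairs", {
  lo <- flat_bundle("c1", 2.2, 1.6)
  hi_other <- flat_bundle("c2", 16.7, 1.2)
  expect_error(extract_cell_features(lo, hi_other, flat_donor), "mixes cells")
  hi <- flat_bundle("c1", 16.7, 1.2)
  expect_error(extract_cell_features(hi, lo, flat_donor),
               "2.2 then 16.7")
})

test_that("build_feature_matrix layouts and canonical ordering", {
  recs <- lapply(c("c2", "c1"), function(id)
    extract_cell_features(flat_bundle(id, 2.2, 1.6),
                          flat_bundle(id, 16.7, 1.2),
                          flat_donor, label = "alpha"))
  per_cond <- build_feature_matrix(recs)
  expect_equal(nrow(per_cond), 4L)
  expect_equal(per_cond$cell_id, c("c1", "c1", "c2", "c2")) # sorted
  expect_setequal(per_cond$exp_glucose[per_cond$cell_id == "c1"], c(0, 1))
  expect_equal(per_cond$condition[per_cond$exp_glucose == 0],
               rep("2.2", 2))
  # shuffled input gives the identical matrix
  expect_equal(build_feature_matrix(rev(recs)), per_cond)
  per_cell <- build_feature_matrix(recs, layout = "per_cell")
  expect_equal(nrow(per_cell), 2L)
  expect_true(all(is.na(per_cell$exp_glucose)))
  expect_equal(per_cell$condition, rep("both", 2))
})

test_that("build_feature_matrix handles empty input and mixed schemas", {
  empty <- build_feature_matrix(list())
  expect_equal(nrow(empty), 0L)
  expect_equal(ncol(empty), 156L) # 5 identifier/label columns + 151 features
  rec <- extract_cell_features(flat_bundle("c1", 2.2, 1.6),
                               flat_bundle("c1", 16.7, 1.2), flat_donor)
  bad <- rec
  names(bad$features)[1] <- "not_a_feature"
  expect_error(build_feature_matrix(list(rec, bad)), "mixed feature schemas")
})

test_that("feature_columns finds exactly the schema columns", {
  fm <- fx_fm_small()
  expect_identical(feature_columns(fm), feature_schema()$name)
  expect_identical(feature_columns(fm[, 1:5]), character(0))
})

test_that("write_feature_matrix emits a CSV plus schema sidecar", {
  path <- file.path(tempdir(), "fm.csv")
  on.exit(unlink(c(path, paste0(path, ".schema.json"))))
  write_feature_matrix(fx_fm_small(), path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".schema.json")))
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(fx_fm_small()))
})
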