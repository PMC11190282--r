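test_that("clean_records partitions by manifest and drops duplicates", {
  fm <- fx_fm_small()
  ids <- unique(fm$cell_id)
  mf <- tibble::tibble(cell_id = ids[1:3],
                       reason = c("duplicate", "shape-change",
                                  "ambiguous-identity"))
  cl <- clean_records(fm, mf)
  expect_s3_class(cl, "cleaning_result")
  expect_equal(nrow(cl$excluded), 6L) # 3 cells x 2 conditions
  expect_equal(nrow(cl$retained), nrow(fm) - 6L)
  expect_false(any(cl$retained$cell_id %in% mf$cell_id))
  # duplicated rows in the retained partition are dropped
  dup <- clean_records(rbind(fm, fm[1, ]), mf)
  expect_equal(nrow(dup$retained), nrow(cl$retained))
  # empty manifest keeps everything
  expect_equal(nrow(clean_records(fm, NULL)$retained), nrow(fm))
  expect_error(clean_records(fm, tibble::tibble(cell_id = "nope",
                                                reason = "duplicate")),
               "unknown cell id")
  expect_error(clean_records(fm, tibble::tibble(cell_id = ids[1],
                                                reason = "bad-code")),
               "unknown reason")
})

test_that("impute_missing zeroes NA/NaN and nothing else", {
  m <- matrix(c(1, NA, NaN, 4), 2)
  expect_equal(impute_missing(m), matrix(c(1, 0, 0, 4), 2))
  d <- tibble::tibble(a = c(1, NA), b = c(NaN, 2))
  di <- impute_missing(d)
  expect_equal(di$a, c(1, 0))
  expect_equal(di$b, c(0, 2))
})

test_that("lof_scores flags an isolated point, not grid interiors", {
  grid <- as.matrix(expand.grid(x = 1:7, y = 1:7))
  x <- rbind(grid, c(30, 30))
  sc <- lof_scores(x, n_neighbors = 5)
  expect_equal(length(sc), 50L)
  expect_gt(sc[50], 1.5)
  expect_lt(median(sc[1:49]), 1.2)
  expect_error(lof_scores(grid[1:4, ], n_neighbors = 5))
})

test_that("replace_outliers substitutes flagged rows with inlier means", {
  set.seed(1)
  x <- matrix(rnorm(40 * 3), 40)
  x[1, ] <- c(50, -50, 50)
  out <- replace_outliers(x, n_neighbors = 10)
  expect_true(out$flagged[1])
  inlier_means <- unname(colMeans(x[!out$flagged, ]))
  # every flagged row is replaced by the inlier means ...
  for (i in which(out$flagged))
    expect_equal(unlist(out$data[i, ], use.names = FALSE), inlier_means)
  # ... and non-flagged rows are untouched
  expect_equal(as.matrix(out$data[!out$flagged, ]), x[!out$flagged, ],
               ignore_attr = TRUE)
  expect_warning(replace_outliers(x[1:5, ], n_neighbors = 10), "too few")
})

test_that("min-max state maps train to [0,1] and leaves test unclipped", {
  train <- tibble::tibble(a = c(0, 5, 10), b = c(2, 2, 2))
  st <- fit_preprocess(train)
  expect_s3_class(st, "preprocess_state")
  tr <- apply_preprocess(st, train)
  expect_equal(tr$a, c(0, 0.5, 1))
  expect_equal(tr$b, c(0, 0, 0)) # constant feature maps to 0
  te <- apply_preprocess(st, tibble::tibble(a = 20, b = 3))
  expect_equal(te$a, 2) # out-of-range values are not clipped
  expect_error(apply_preprocess(st, tibble::tibble(a = 1)), "lacks fitted")
})

test_that("split_stratified rounds per class: 861 rows give 216 test rows", {
  labels <- rep(c("alpha", "beta"), c(287, 574))
  sp <- split_stratified(labels, test_fraction = 0.25, seed = 2)
  expect_equal(length(sp$test), round(287 * 0.25) + round(574 * 0.25))
  expect_equal(length(sp$test), 216L)
  expect_equal(length(intersect(sp$train, sp$test)), 0L)
  expect_equal(sort(c(sp$train, sp$test)), 1:861)
  expect_equal(sum(labels[sp$test] == "alpha"), 72L)
  expect_equal(split_stratified(labels, 0.25, seed = 2)$test, sp$test)
})

test_that("SMOTE balances 2:1 to 1:1 with convex synthetic rows", {
  set.seed(6)
  x <- matrix(runif(900 * 4), 900)
  colnames(x) <- paste0("f", 1:4)
  y <- factor(rep(c("beta", "alpha"), c(600, 300)),
              levels = c("alpha", "beta"))
  sm <- rebalance_smote(x, y, seed = 3)
  expect_equal(sm$n_synthetic, 300L)
  expect_equal(unname(table(sm$labels)[["alpha"]]),
               unname(table(sm$labels)[["beta"]]))
  # originals first and bit-identical
  expect_identical(as.matrix(sm$data[1:900, ]), x, ignore_attr = TRUE)
  # synthetic rows stay inside the minority bounding box
  syn <- as.matrix(sm$data[901:1200, ])
  minr <- x[y == "alpha", ]
  for (j in 1:4) {
    expect_true(all(syn[, j] >= min(minr[, j]) - 1e-12))
    expect_true(all(syn[, j] <= max(minr[, j]) + 1e-12))
  }
  # balanced input is returned untouched
  bal <- rebalance_smote(x[1:600, ], factor(rep(c("alpha", "beta"), 300),
                                            levels = c("alpha", "beta")))
  expect_equal(bal$n_synthetic, 0L)
  # tiny minority class reduces the neighbourhood with a warning
  expect_warning(
    rebalance_smote(x[1:104, ], factor(rep(c("beta", "alpha"), c(100, 4)),
                                       levels = c("alpha", "beta"))),
    "reducing k_neighbors")
})

test_that("encode_donor_onehot appends indicator columns", {
  d <- tibble::tibble(donor_id = c("D01", "D02", "D01"), v = 1:3)
  e <- encode_donor_onehot(d)
  expect_equal(e$donor_D01, c(1, 0, 1))
  expect_equal(e$donor_D02, c(0, 1, 0))
})

test_that("preprocess_split fits its state on the training partition only", {
  fm <- fx_fm_small() # 80 rows
  pr <- preprocess_split(fm, seed = 4)
  expect_s3_class(pr, "preprocess_result")
  expect_equal(length(pr$test$y), nrow(pr$test$x))
  expect_equal(length(pr$train$y), nrow(pr$train$x))
  # training classes are balanced after SMOTE
  expect_equal(unname(diff(table(pr$train$y))), 0L)
  # the state was fitted on the (imputed, outlier-replaced) train partition:
  # scaled training features never leave [0,1]; test rows may
  feats_range <- range(as.matrix(pr$train$x))
  expect_gte(feats_range[1], 0)
  expect_lte(feats_range[2], 1)
  expect_identical(pr$state$fitted_on, "train")
  # held-out rows and training rows are disjoint
  expect_equal(length(intersect(pr$split$train, pr$split$test)), 0L)
  # paper-faithful variant fits on the full matrix
  pf <- preprocess_split(fm, seed = 4, paper_faithful = TRUE)
  expect_identical(pf$state$fitted_on, "full")
  # deterministic
  pr2 <- preprocess_split(fm, seed = 4)
  expect_equal(pr$train$x, pr2$train$x)
  expect_equal(pr$test$y, pr2$test$y)
})
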