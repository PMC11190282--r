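test_that("specification constructors validate their arguments", {
  sp <- model_spec("boosted_trees")
  expect_s3_class(sp, "model_spec")
  expect_true(all(c("nrounds", "max_depth", "eta") %in% names(sp$grid)))
  expect_error(model_spec("random_forest"))
  expect_error(model_spec("knn", grid = list()))
  cv <- cv_spec(5, 3, seed = 2)
  expect_s3_class(cv, "cv_spec")
  expect_error(cv_spec(1))
  se <- search_spec("sampled", budget = 10)
  expect_s3_class(se, "search_spec")
  expect_error(search_spec(budget = 0))
})

test_that("make_folds stratifies every class across folds", {
  y <- factor(rep(c("alpha", "beta"), c(20, 40)))
  folds <- isletcytotyper:::make_folds(y, n_folds = 5, n_repeats = 2, seed = 1)
  expect_equal(length(folds), 2L)
  for (f in folds) {
    expect_equal(sort(unique(f)), 1:5)
    for (k in 1:5) {
      expect_equal(sum(f == k & y == "alpha"), 4L)
      expect_equal(sum(f == k & y == "beta"), 8L)
    }
  }
  expect_error(isletcytotyper:::make_folds(factor(rep(c("a", "b"), c(3, 40))),
                                           5, 1, 1),
               "fewer members than folds")
})

test_that("every model family learns a separable toy problem", {
  d <- fx_gauss(40, 40, sep = 3, seed = 5)
  d_new <- fx_gauss(30, 30, sep = 3, seed = 6)
  for (fam in c("boosted_trees", "logistic", "svm", "knn")) {
    m <- isletcytotyper:::fit_model(fam, list(), d$x, d$y, seed = 2)
    expect_s3_class(m, "islet_model")
    pr <- predict(m, d_new$x)
    expect_true(all(c(".prob_beta", ".pred_class") %in% names(pr)))
    expect_true(all(pr$.prob_beta >= 0 & pr$.prob_beta <= 1))
    expect_equal(levels(pr$.pred_class), c("alpha", "beta"))
    auc <- isletcytotyper:::auc_score(d_new$y, pr$.prob_beta)
    expect_gt(auc, 0.9)
  }
})

test_that("grid search evaluates the full grid and is reproducible", {
  d <- fx_gauss(30, 30, sep = 2, seed = 7)
  sp <- model_spec("logistic", grid = list(lambda = c(1e-3, 1e-1)))
  cv <- cv_spec(3, 1, seed = 4)
  fit <- cross_validate(d$x, d$y, sp, cv, search_spec("grid"))
  expect_s3_class(fit, "islet_cv")
  expect_equal(nrow(fit$cv_table), 2L)
  expect_false(any(fit$cv_table$pruned))
  expect_equal(fit$best_score, max(fit$cv_table$mean_auc))
  expect_equal(length(fit$fold_scores), 3L)
  expect_true(fit$best_params$lambda %in% c(1e-3, 1e-1))
  fit2 <- cross_validate(d$x, d$y, sp, cv, search_spec("grid"))
  expect_equal(fit2$cv_table, fit$cv_table)
  # the refit model predicts the training data well
  expect_gt(evaluate_model(fit, d$x, d$y)$roc_auc, 0.9)
})

test_that("sampled search respects the budget and records pruning", {
  d <- fx_gauss(30, 30, sep = 2, seed = 8)
  sp <- model_spec("knn", grid = list(k = seq(3, 21, 2)))
  cv <- cv_spec(3, 2, seed = 5)
  fit <- cross_validate(d$x, d$y, sp, cv,
                        search_spec("sampled", budget = 4, seed = 6))
  expect_equal(nrow(fit$cv_table), 4L)
  expect_true(all(fit$cv_table$n_folds_run %in% c(3L, 6L)))
  # pruned trials never stop after the first repeat
  expect_true(all(fit$cv_table$n_folds_run[fit$cv_table$pruned] == 3L))
  # the winner is the best non-pruned trial
  expect_equal(fit$best_score,
               max(fit$cv_table$mean_auc[!fit$cv_table$pruned]))
})

test_that("importance_ranking isolates the informative feature", {
  set.seed(9)
  n <- 120
  x <- cbind(signal = rep(c(0, 1), each = n / 2) + rnorm(n, sd = 0.1),
             noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
  y <- factor(rep(c("alpha", "beta"), each = n / 2),
              levels = c("alpha", "beta"))
  m <- isletcytotyper:::fit_model("boosted_trees",
                                  list(nrounds = 40, max_depth = 3),
                                  x, y, seed = 3)
  imp <- importance_ranking(m)
  expect_s3_class(imp, "islet_importance")
  expect_equal(imp$feature[1], "signal")
  expect_equal(nrow(imp), 4L)
  expect_equal(sum(imp$importance), 1)
  expect_equal(imp$rank, 1:4)
  lm <- isletcytotyper:::fit_model("logistic", list(), x, y)
  expect_error(importance_ranking(lm), "boosted trees")
})

test_that("feature_cutoff_sweep picks the smallest tied subset", {
  d <- fx_gauss(30, 30, d = 6, sep = 3, seed = 10)
  sp <- model_spec("logistic", grid = list(lambda = 1e-2))
  cv <- cv_spec(3, 1, seed = 2)
  rank6 <- tibble::tibble(rank = 1:6, feature = colnames(d$x),
                          importance = rep(1 / 6, 6))
  class(rank6) <- c("islet_importance", class(rank6))
  sw <- feature_cutoff_sweep(d$x, d$y, rank6, cutoffs = c(2, 6), sp, cv,
                             search_spec("grid"))
  expect_s3_class(sw, "islet_sweep")
  expect_equal(sw$table$cutoff, c(2L, 6L))
  expect_equal(length(sw$best_features), sw$best_cutoff)
  expect_s3_class(sw$best_fit, "islet_cv")
  expect_error(feature_cutoff_sweep(d$x, d$y, rank6, cutoffs = 9, sp, cv))
})
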