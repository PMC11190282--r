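#' Model, cross-validation and search specifications
#'
#' `model_spec()` declares one of the four classifier families and its
#' hyperparameter grid; `cv_spec()` the repeated stratified k-fold scheme;
#' `search_spec()` the tuning strategy. The beta class is always the
#' positive class.
#'
#' Default grids are compact, commonly used ranges per family:
#' * `boosted_trees` (xgboost): `nrounds` 60/120, `max_depth` 2/3/4/6,
#'   `eta` 0.05/0.1/0.3, `min_child_weight` 1/3;
#' * `logistic` (ridge-regularised): `lambda` 1e-4..1e-1;
#' * `svm` (RBF): `cost` 0.1/1/10, `gamma` 0.01/0.1/1;
#' * `knn`: odd `k` 3..21.
#'
#' @param family one of `"boosted_trees"`, `"logistic"`, `"svm"`, `"knn"`.
#' @param grid named list of parameter vectors (crossed); `NULL` uses the
#'   family default.
#' @param class_weight `"none"` (default, appropriate when SMOTE already
#'   balanced the classes) or `"balanced"`.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(family = c("boosted_trees", "logistic", "svm", "knn"),
                       grid = NULL, class_weight = c("none", "balanced")) {
  family <- match.arg(family)
  class_weight <- match.arg(class_weight)
  if (is.null(grid)) grid <- default_grid(family)
  stopifnot(is.list(grid), length(grid) > 0, all(lengths(grid) >= 1))
  structure(list(family = family, grid = grid, class_weight = class_weight),
            class = "model_spec")
}

default_grid <- function(family) {
  switch(family,
    boosted_trees = list(nrounds = c(60, 120), max_depth = c(2, 3, 4, 6),
                         eta = c(0.05, 0.1, 0.3), min_child_weight = c(1, 3)),
    logistic = list(lambda = c(1e-4, 1e-3, 1e-2, 1e-1)),
    svm = list(cost = c(0.1, 1, 10), gamma = c(0.01, 0.1, 1)),
    knn = list(k = c(3, 5, 7, 11, 15, 21)))
}

#' @rdname model_spec
#' @param n_folds number of folds (5 or 10 in the study design).
#' @param n_repeats number of repetitions.
#' @param seed integer seed for fold assignment.
#' @export
cv_spec <- function(n_folds = 5L, n_repeats = 3L, seed = 1L) {
  stopifnot(n_folds >= 2L, n_repeats >= 1L)
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "cv_spec")
}

#' @rdname model_spec
#' @param strategy `"grid"` evaluates the whole grid; `"sampled"` draws
#'   `budget` seeded configurations from it with median-rule pruning after
#'   the first cross-validation repeat.
#' @param budget maximum trials for the sampled strategy.
#' @param pruning enable median-rule pruning (sampled strategy only).
#' @export
search_spec <- function(strategy = c("grid", "sampled"), budget = 50L,
                        pruning = TRUE, seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(budget >= 1L)
  structure(list(strategy = strategy, budget = as.integer(budget),
                 pruning = isTRUE(pruning), seed = as.integer(seed)),
            class = "search_spec")
}

# Stratified fold ids: one integer vector per repeat, classes balanced
# across folds.
make_folds <- function(y, n_folds, n_repeats, seed) {
  y <- as.factor(y)
  if (any(table(y) < n_folds))
    stop("make_folds(): a class has fewer members than folds")
  set.seed(seed)
  lapply(seq_len(n_repeats), function(r) {
    fold <- integer(length(y))
    for (lv in levels(y)) {
      rows <- sample(which(y == lv))
      fold[rows] <- rep(seq_len(n_folds), length.out = length(rows))
    }
    fold
  })
}

# --- family-specific fit / predict -----------------------------------------

fit_model <- function(family, params, x, y, class_weight = "none",
                      seed = 1L) {
  x <- as.matrix(x)
  y <- factor(y, levels = c("alpha", "beta"))
  set.seed(seed)
  fit <- switch(family,
    boosted_trees = {
      w <- if (class_weight == "balanced")
        sum(y == "alpha") / sum(y == "beta") else 1
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eval_metric = "auc",
                      max_depth = as.integer(params$max_depth %||% 6),
                      eta = params$eta %||% 0.3,
                      min_child_weight = params$min_child_weight %||% 1,
                      scale_pos_weight = w, nthread = 1, seed = seed),
        data = xgboost::xgb.DMatrix(x, label = as.integer(y == "beta")),
        nrounds = as.integer(params$nrounds %||% 100), verbose = 0)
    },
    logistic = {
      w <- rep(1, length(y))
      if (class_weight == "balanced")
        w <- length(y) / (2 * table(y)[as.character(y)])
      glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                     lambda = params$lambda %||% 1e-3, weights = as.numeric(w))
    },
    svm = {
      cw <- if (class_weight == "balanced") {
        tab <- table(y); setNames(as.numeric(sum(tab) / (2 * tab)), names(tab))
      } else NULL
      e1071::svm(x, y, kernel = "radial", cost = params$cost %||% 1,
                 gamma = params$gamma %||% (1 / ncol(x)),
                 class.weights = cw, scale = FALSE)
    },
    knn = list(x = x, y = y, k = as.integer(params$k %||% 5)),
    stop("unknown model family: ", family))
  structure(list(family = family, params = params, fit = fit,
                 features = colnames(x), seed = seed),
            class = "islet_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Probability of the beta class per row.
predict_prob <- function(model, x) {
  x <- as.matrix(x)[, model$features, drop = FALSE]
  switch(model$family,
    boosted_trees = as.numeric(predict(model$fit, xgboost::xgb.DMatrix(x))),
    logistic = as.numeric(predict(model$fit, x, type = "response")),
    svm = {
      dv <- attr(predict(model$fit, x, decision.values = TRUE),
                 "decision.values")
      # orient the margin so positive means beta, then squash
      sgn <- if (grepl("^beta", colnames(dv)[1])) 1 else -1
      as.numeric(plogis(sgn * dv[, 1]))
    },
    knn = {
      set.seed(model$seed)
      pr <- class::knn(model$fit$x, x, model$fit$y, k = model$fit$k,
                       prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "beta", p, 1 - p)
    })
}

#' Predict cell identity with a fitted model
#'
#' @param object an `islet_model` or `islet_cv` fit.
#' @param new_data feature table transformed by the training
#'   `preprocess_state`.
#' @param threshold classification threshold on the beta probability.
#' @param ... unused.
#' @return tibble: `.prob_beta`, `.pred_class` (factor alpha/beta), row
#'   order preserved.
#' @export
predict.islet_model <- function(object, new_data, threshold = 0.5, ...) {
  p <- predict_prob(object, new_data)
  tibble(.prob_beta = p,
         .pred_class = factor(ifelse(p >= threshold, "beta", "alpha"),
                              levels = c("alpha", "beta")))
}

#' @rdname predict.islet_model
#' @export
predict.islet_cv <- function(object, new_data, threshold = 0.5, ...) {
  predict(object$model, new_data, threshold = threshold, ...)
}

# AUC of probabilities against labels; NA when only one class present.
auc_score <- function(y, p) {
  y <- factor(y, levels = c("alpha", "beta"))
  if (nlevels(droplevels(y)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                 levels = c("alpha", "beta"),
                                 direction = "<")))
}

#' Hyperparameter search under repeated stratified cross-validation
#'
#' Evaluates hyperparameter configurations of one model family by mean ROC
#' AUC over repeated stratified k-fold cross-validation, then refits the
#' best configuration on the full training partition. The `grid` strategy
#' evaluates every configuration; `sampled` draws `budget` configurations at
#' random (seeded) and, when pruning is on, abandons a configuration after
#' the first repeat if its running mean falls below the median of previously
#' completed trials.
#'
#' @param x training features (rows aligned with `y`), already preprocessed.
#' @param y training labels, factor alpha/beta; every fold must contain both
#'   classes.
#' @param spec a [model_spec()].
#' @param cv a [cv_spec()].
#' @param search a [search_spec()].
#' @return list of class `islet_cv`: `model` (refit `islet_model`),
#'   `best_params`, `best_score`, `cv_table` (one row per trial: parameters,
#'   mean/sd AUC, folds evaluated, pruned flag), `fold_scores` of the best
#'   trial, `spec`, `cv`, `search`.
#' @export
cross_validate <- function(x, y, spec, cv = cv_spec(), search = search_spec()) {
  stopifnot(inherits(spec, "model_spec"), inherits(cv, "cv_spec"),
            inherits(search, "search_spec"))
  x <- as.matrix(x)
  y <- factor(y, levels = c("alpha", "beta"))
  folds <- make_folds(y, cv$n_folds, cv$n_repeats, cv$seed)
  grid_df <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
  if (search$strategy == "sampled" && nrow(grid_df) > search$budget) {
    set.seed(search$seed)
    grid_df <- grid_df[sample(nrow(grid_df), search$budget), , drop = FALSE]
  }
  eval_fold <- function(params, rep_i, fold_i) {
    test_rows <- which(folds[[rep_i]] == fold_i)
    if (nlevels(droplevels(y[-test_rows])) < 2L ||
        nlevels(droplevels(y[test_rows])) < 2L)
      stop("cross_validate(): a fold lacks a class (stratification bug)")
    m <- fit_model(spec$family, params, x[-test_rows, , drop = FALSE],
                   y[-test_rows], spec$class_weight,
                   seed = derive_seed(cv$seed, paste0("fit", rep_i, "_", fold_i)))
    auc_score(y[test_rows], predict_prob(m, x[test_rows, , drop = FALSE]))
  }
  results <- vector("list", nrow(grid_df))
  completed_first <- numeric(0)
  for (tr in seq_len(nrow(grid_df))) {
    params <- as.list(grid_df[tr, , drop = FALSE])
    scores <- numeric(0)
    pruned <- FALSE
    for (rep_i in seq_len(cv$n_repeats)) {
      scores <- c(scores, vapply(seq_len(cv$n_folds), function(f)
        eval_fold(params, rep_i, f), 0))
      if (rep_i == 1L && search$strategy == "sampled" && search$pruning &&
          length(completed_first) >= 3L &&
          mean(scores) < median(completed_first)) {
        pruned <- TRUE
        break
      }
    }
    if (length(scores) >= cv$n_folds)
      completed_first <- c(completed_first, mean(scores[seq_len(cv$n_folds)]))
    results[[tr]] <- tibble(trial = tr, mean_auc = mean(scores),
                            sd_auc = if (length(scores) > 1) sd(scores) else NA_real_,
                            n_folds_run = length(scores), pruned = pruned)
    results[[tr]] <- dplyr::bind_cols(results[[tr]],
                                      as_tibble(grid_df[tr, , drop = FALSE]))
  }
  cv_table <- dplyr::bind_rows(results)
  eligible <- dplyr::filter(cv_table, !.data$pruned)
  best_row <- eligible[order(-eligible$mean_auc, eligible$trial), ][1, ]
  best_params <- as.list(grid_df[best_row$trial, , drop = FALSE])
  # per-fold scores of the winner (recomputed for the report)
  fold_scores <- unlist(lapply(seq_len(cv$n_repeats), function(r)
    vapply(seq_len(cv$n_folds), function(f) eval_fold(best_params, r, f), 0)))
  model <- fit_model(spec$family, best_params, x, y, spec$class_weight,
                     seed = derive_seed(cv$seed, "refit"))
  structure(list(model = model, best_params = best_params,
                 best_score = best_row$mean_auc, cv_table = cv_table,
                 fold_scores = fold_scores, spec = spec, cv = cv,
                 search = search),
            class = "islet_cv")
}

#' Gain-based feature importance ranking of a boosted-tree model
#'
#' Normalized gain importances sorted non-increasingly; features the model
#' never split on are appended with importance 0 so the ranking covers the
#' full schema. Scores sum to 1.
#'
#' @param model an `islet_model` or `islet_cv` of the boosted-trees family.
#' @return tibble of class `islet_importance`: `rank`, `feature`,
#'   `importance`.
#' @export
importance_ranking <- function(model) {
  if (inherits(model, "islet_cv")) model <- model$model
  stopifnot(inherits(model, "islet_model"))
  if (model$family != "boosted_trees")
    stop("importance_ranking(): gain importances exist only for boosted trees")
  imp <- xgboost::xgb.importance(model = model$fit)
  out <- tibble(feature = imp$Feature, importance = imp$Gain)
  rest <- setdiff(model$features, out$feature)
  out <- dplyr::bind_rows(out, tibble(feature = rest,
                                      importance = rep(0, length(rest))))
  out <- dplyr::arrange(out, dplyr::desc(.data$importance))
  out$rank <- seq_len(nrow(out))
  structure(dplyr::select(out, "rank", "feature", "importance"),
            class = c("islet_importance", class(out)))
}

#' Importance-cutoff feature-selection sweep
#'
#' Retrains and cross-validates the model on the top-`cutoff` features of an
#' importance ranking, for each cutoff, and picks the best subset by mean CV
#' AUC (ties broken toward fewer features).
#'
#' @param x,y training data.
#' @param ranking an `islet_importance` ranking.
#' @param cutoffs integer feature counts to try.
#' @param spec,cv,search as in [cross_validate()].
#' @return list of class `islet_sweep`: `table` (tibble `cutoff`,
#'   `mean_auc`, `sd_auc`), `best_cutoff`, `best_features`, `best_fit`
#'   (the winning `islet_cv`).
#' @export
feature_cutoff_sweep <- function(x, y, ranking, cutoffs, spec,
                                 cv = cv_spec(), search = search_spec()) {
  stopifnot(all(cutoffs >= 1), all(cutoffs <= nrow(ranking)))
  cutoffs <- sort(unique(as.integer(cutoffs)))
  fits <- lapply(cutoffs, function(ct) {
    feats <- ranking$feature[seq_len(ct)]
    cross_validate(as.matrix(x)[, feats, drop = FALSE], y, spec, cv, search)
  })
  tab <- tibble(cutoff = cutoffs,
                mean_auc = vapply(fits, function(f) f$best_score, 0),
                sd_auc = vapply(fits, function(f) sd(f$fold_scores), 0))
  best_i <- which(tab$mean_auc == max(tab$mean_auc))[1] # ties: fewest features
  structure(list(table = tab, best_cutoff = cutoffs[best_i],
                 best_features = ranking$feature[seq_len(cutoffs[best_i])],
                 best_fit = fits[[best_i]]),
            class = "islet_sweep")
}
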