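#' Classification metrics from labels and beta probabilities
#'
#' ROC AUC plus per-class precision, recall and F1 (beta and alpha reported
#' separately), accuracy and the confusion counts, at a fixed probability
#' threshold. Metrics with zero denominators are reported as `NA`, never
#' silently 0; a single-class truth vector yields `roc_auc = NA`.
#'
#' @param truth factor with levels alpha/beta.
#' @param prob_beta probability of the beta class per row.
#' @param threshold classification threshold (default 0.5).
#' @return list of class `islet_metrics`: `roc_auc`, `accuracy`, `per_class`
#'   (tibble `class`, `precision`, `recall`, `f1`), `confusion` (tp, fp, fn,
#'   tn with beta as positive), `n_test`, `threshold`.
#' @export
compute_metrics <- function(truth, prob_beta, threshold = 0.5) {
  truth <- factor(truth, levels = c("alpha", "beta"))
  stopifnot(length(truth) == length(prob_beta))
  pred <- factor(ifelse(prob_beta >= threshold, "beta", "alpha"),
                 levels = c("alpha", "beta"))
  tp <- sum(pred == "beta" & truth == "beta")
  fp <- sum(pred == "beta" & truth == "alpha")
  fn <- sum(pred == "alpha" & truth == "beta")
  tn <- sum(pred == "alpha" & truth == "alpha")
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  prf <- function(tp_, fp_, fn_) {
    p <- safe_div(tp_, tp_ + fp_)
    r <- safe_div(tp_, tp_ + fn_)
    f <- if (!is.na(p) && !is.na(r) && (p + r) > 0) 2 * p * r / (p + r)
         else NA_real_
    c(precision = p, recall = r, f1 = f)
  }
  beta_m <- prf(tp, fp, fn)
  alpha_m <- prf(tn, fn, fp)
  structure(list(
    roc_auc = auc_score(truth, prob_beta),
    accuracy = (tp + tn) / length(truth),
    per_class = tibble(class = c("alpha", "beta"),
                       precision = unname(c(alpha_m["precision"],
                                            beta_m["precision"])),
                       recall = unname(c(alpha_m["recall"], beta_m["recall"])),
                       f1 = unname(c(alpha_m["f1"], beta_m["f1"]))),
    confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
    n_test = length(truth), threshold = threshold
  ), class = "islet_metrics")
}

#' Held-out evaluation of a fitted model
#'
#' @param model an `islet_model` or `islet_cv`.
#' @param x_test,y_test held-out features (transformed by the training
#'   `preprocess_state`) and labels.
#' @param threshold classification threshold.
#' @return an `islet_metrics` report (see [compute_metrics()]). An empty
#'   test set returns an empty report (`n_test = 0`) without error.
#' @export
evaluate_model <- function(model, x_test, y_test, threshold = 0.5) {
  if (NROW(x_test) == 0L) {
    return(structure(list(roc_auc = NA_real_, accuracy = NA_real_,
                          per_class = tibble(class = c("alpha", "beta"),
                                             precision = NA_real_,
                                             recall = NA_real_, f1 = NA_real_),
                          confusion = c(tp = 0L, fp = 0L, fn = 0L, tn = 0L),
                          n_test = 0L, threshold = threshold),
                     class = "islet_metrics"))
  }
  p <- if (inherits(model, "islet_cv")) predict(model, x_test)$.prob_beta
       else predict(model, x_test)$.prob_beta
  compute_metrics(y_test, p, threshold)
}

#' Label-shuffle (Salzberg) stability test
#'
#' Permutes the training labels, reruns the identical tuning pipeline
#' (same model family, grid, cross-validation scheme and budget), and
#' evaluates the noise-trained model. Near-chance performance of the
#' shuffled run certifies that the real pipeline's score does not come from
#' leakage or overfitting. Reports shuffled CV, shuffled-train and test
#' metrics and, when a reference report is supplied, the relative drop.
#'
#' @param x_train,y_train,x_test,y_test preprocessed partitions.
#' @param spec,cv,search the pipeline configuration of the real run.
#' @param seed permutation seed. `permutation` may instead give an explicit
#'   permutation of `seq_along(y_train)`; the identity permutation
#'   reproduces the real run exactly.
#' @param reference optional `islet_metrics` of the real (unshuffled) run.
#' @param permutation optional explicit permutation.
#' @return list of class `islet_salzberg`: `fit` (`islet_cv` on shuffled
#'   labels), `cv_auc`, `train_metrics` (on shuffled training labels),
#'   `test_metrics` (on true test labels), `reference`, `relative_drop`
#'   (1 - shuffled/reference test AUC, `NA` without a reference).
#' @export
salzberg_test <- function(x_train, y_train, x_test, y_test, spec,
                          cv = cv_spec(), search = search_spec(),
                          seed = 1L, reference = NULL, permutation = NULL) {
  if (is.null(permutation)) {
    set.seed(seed)
    permutation <- sample(seq_along(y_train))
  }
  stopifnot(length(permutation) == length(y_train))
  y_shuf <- y_train[permutation]
  fit <- cross_validate(x_train, y_shuf, spec, cv, search)
  train_metrics <- evaluate_model(fit, x_train, y_shuf)
  test_metrics <- evaluate_model(fit, x_test, y_test)
  drop <- if (!is.null(reference) && is.finite(reference$roc_auc))
    1 - test_metrics$roc_auc / reference$roc_auc else NA_real_
  structure(list(fit = fit, cv_auc = fit$best_score,
                 train_metrics = train_metrics, test_metrics = test_metrics,
                 reference = reference, relative_drop = drop),
            class = "islet_salzberg")
}

#' Classify records excluded during dataset cleaning
#'
#' Applies the trained model to the cleaning-excluded partition (transformed
#' by the same fitted preprocessing state). When exclusion correlates with
#' label noise, these metrics are expected to fall below the clean-test
#' report, validating the cleaning procedure.
#'
#' @param model fitted `islet_model` / `islet_cv`.
#' @param excluded feature tibble (the `excluded` element of
#'   [clean_records()]), with `cell_type` labels.
#' @param state the training `preprocess_state`.
#' @param threshold classification threshold.
#' @return an `islet_metrics` report; empty input gives an empty report.
#' @export
classify_excluded <- function(model, excluded, state, threshold = 0.5) {
  if (NROW(excluded) == 0L)
    return(evaluate_model(model, excluded[0, feature_columns(excluded)],
                          factor(character(), levels = c("alpha", "beta")),
                          threshold))
  x <- apply_preprocess(state, impute_missing(excluded[, state$features]))
  evaluate_model(model, x, excluded$cell_type, threshold)
}

#' Five- versus ten-fold cross-validation comparison
#'
#' Reruns the full tuning at 10 folds and reports both CV means and their
#' absolute difference; a small difference indicates the tuned score is
#' stable against the fold count.
#'
#' @param x,y training data.
#' @param spec,search as in [cross_validate()].
#' @param cv5 the five-fold [cv_spec()] of the reference run.
#' @return list of class `islet_tenfold`: `table` (tibble `n_folds`,
#'   `mean_auc`, `sd_auc`), `abs_difference`, `fits`.
#' @export
tenfold_variant <- function(x, y, spec, cv5 = cv_spec(5L, 3L),
                            search = search_spec()) {
  cv10 <- cv_spec(10L, cv5$n_repeats, cv5$seed)
  fit5 <- cross_validate(x, y, spec, cv5, search)
  fit10 <- cross_validate(x, y, spec, cv10, search)
  tab <- tibble(n_folds = c(cv5$n_folds, 10L),
                mean_auc = c(fit5$best_score, fit10$best_score),
                sd_auc = c(sd(fit5$fold_scores), sd(fit10$fold_scores)))
  structure(list(table = tab,
                 abs_difference = abs(diff(tab$mean_auc)),
                 fits = list(fold5 = fit5, fold10 = fit10)),
            class = "islet_tenfold")
}
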