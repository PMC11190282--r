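#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates synthesize -> features -> explore -> clean -> preprocess ->
#' train -> evaluate -> stability from one configuration with one global
#' seed (all stage seeds are derived from it), and optionally writes a JSON
#' summary plus CSV artifacts. Rerunning with the same configuration
#' reproduces the summary exactly.
#'
#' @param config a [synth_config()] describing the cohort.
#' @param seed global seed; stage seeds come from [derive_seed()].
#' @param spec,cv,search model and tuning configuration (defaults: boosted
#'   trees, 5x3 repeated stratified CV, sampled search with budget 20).
#' @param manifest optional cleaning manifest (see [clean_records()]).
#' @param test_fraction held-out fraction.
#' @param explore_k_max elbow-scan upper bound.
#' @param salzberg run the label-shuffle stability test (doubles training
#'   cost).
#' @param out_dir optional output directory for the JSON summary, feature
#'   CSV and schema sidecar.
#' @return list of class `islet_run`: `features`, `explore`, `cleaning`,
#'   `prep`, `fit`, `test_metrics`, `importance`, `salzberg`, `summary`
#'   (plain list mirrored to JSON).
#' @export
run_pipeline <- function(config = synth_config(n_cells = 300, seed = 1L),
                         seed = config$seed,
                         spec = model_spec("boosted_trees"),
                         cv = cv_spec(5L, 3L, seed = derive_seed(seed, "cv")),
                         search = search_spec("sampled", budget = 20L,
                                              seed = derive_seed(seed, "search")),
                         manifest = NULL,
                         test_fraction = 0.25,
                         explore_k_max = 20L,
                         salzberg = TRUE,
                         out_dir = NULL) {
  features <- generate_feature_matrix(config)
  explore <- explore_features(features, k_max = explore_k_max,
                              seed = derive_seed(seed, "explore"))
  cleaning <- clean_records(features, manifest)
  prep <- preprocess_split(cleaning$retained, test_fraction = test_fraction,
                           seed = derive_seed(seed, "prep"))
  fit <- cross_validate(prep$train$x, prep$train$y, spec, cv, search)
  test_metrics <- evaluate_model(fit, prep$test$x, prep$test$y)
  importance <- if (spec$family == "boosted_trees")
    importance_ranking(fit) else NULL
  salz <- if (salzberg)
    salzberg_test(prep$train$x, prep$train$y, prep$test$x, prep$test$y,
                  spec, cv, search, seed = derive_seed(seed, "salzberg"),
                  reference = test_metrics) else NULL
  excluded_metrics <- if (nrow(cleaning$excluded) > 0L)
    classify_excluded(fit, cleaning$excluded, prep$state) else NULL
  summary <- list(
    n_rows = nrow(features),
    n_features = length(feature_columns(features)),
    class_counts = as.list(table(features$cell_type)),
    explained_variance_2 = sum(explore$pca$explained_variance),
    knee_k = explore$elbow$knee_k,
    mean_gini = explore$gini$mean_gini,
    cluster_auc = explore$cluster_auc$roc_auc,
    n_retained = nrow(cleaning$retained),
    n_excluded = nrow(cleaning$excluded),
    n_train = length(prep$train$y),
    n_test = length(prep$test$y),
    n_synthetic_smote = prep$n_synthetic,
    cv_auc = fit$best_score,
    best_params = fit$best_params,
    test = list(roc_auc = test_metrics$roc_auc,
                accuracy = test_metrics$accuracy,
                per_class = test_metrics$per_class),
    salzberg = if (!is.null(salz))
      list(cv_auc = salz$cv_auc, test_auc = salz$test_metrics$roc_auc,
           relative_drop = salz$relative_drop) else NULL,
    excluded = if (!is.null(excluded_metrics))
      list(roc_auc = excluded_metrics$roc_auc) else NULL,
    seed = seed
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    write_feature_matrix(features, file.path(out_dir, "features.csv"))
    jsonlite::write_json(config[setdiff(names(config), c(""))],
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  structure(list(features = features, explore = explore, cleaning = cleaning,
                 prep = prep, fit = fit, test_metrics = test_metrics,
                 importance = importance, salzberg = salz,
                 excluded_metrics = excluded_metrics, summary = summary),
            class = "islet_run")
}

#' Predict cell identities for new feature records
#'
#' Applies a trained model plus its fitted preprocessing state to newly
#' extracted (unscaled) feature records.
#'
#' @param model fitted `islet_model` / `islet_cv`.
#' @param state training `preprocess_state`.
#' @param data feature tibble conforming to the model's schema; a schema
#'   mismatch aborts naming the missing features.
#' @param threshold classification threshold.
#' @return tibble: `cell_id` (if present), `prob_beta`, `pred_class`; empty
#'   input gives an empty table.
#' @export
predict_cells <- function(model, state, data, threshold = 0.5) {
  ids <- if ("cell_id" %in% names(data)) data$cell_id else
    as.character(seq_len(NROW(data)))
  if (NROW(data) == 0L)
    return(tibble(cell_id = character(), prob_beta = numeric(),
                  pred_class = factor(character(),
                                      levels = c("alpha", "beta"))))
  x <- apply_preprocess(state, impute_missing(data[, state$features]))
  pr <- predict(model, x, threshold = threshold)
  tibble(cell_id = ids, prob_beta = pr$.prob_beta, pred_class = pr$.pred_class)
}
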