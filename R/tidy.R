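#' Tidy and glance methods
#'
#' broom-style accessors for the package's fitted objects.
#'
#' @param x a fitted object.
#' @param ... unused.
#' @return a tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy islet_cv
#' @export
tidy.islet_cv <- function(x, ...) x$cv_table

#' @rdname tidiers
#' @method glance islet_cv
#' @export
glance.islet_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble(family = x$spec$family, mean_auc = x$best_score,
           sd_auc = sd(x$fold_scores),
           n_folds = x$cv$n_folds, n_repeats = x$cv$n_repeats,
           n_trials = nrow(x$cv_table)),
    as_tibble(x$best_params))
}

#' @rdname tidiers
#' @method tidy islet_metrics
#' @export
tidy.islet_metrics <- function(x, ...) {
  tidyr::pivot_longer(x$per_class, -"class",
                      names_to = "metric", values_to = "value")
}

#' @rdname tidiers
#' @method glance islet_metrics
#' @export
glance.islet_metrics <- function(x, ...) {
  tibble(roc_auc = x$roc_auc, accuracy = x$accuracy, n_test = x$n_test,
         threshold = x$threshold)
}

#' @rdname tidiers
#' @method tidy islet_gini
#' @export
tidy.islet_gini <- function(x, ...) x$per_cluster

#' @rdname tidiers
#' @method glance islet_gini
#' @export
glance.islet_gini <- function(x, ...) {
  tibble(mean_gini = x$mean_gini, n_clusters = nrow(x$per_cluster))
}

#' @rdname tidiers
#' @method tidy islet_elbow
#' @export
tidy.islet_elbow <- function(x, ...) x$curve

#' @rdname tidiers
#' @method glance islet_elbow
#' @export
glance.islet_elbow <- function(x, ...) {
  tibble(knee_k = x$knee_k, low_confidence = x$low_confidence)
}

#' @rdname tidiers
#' @method tidy islet_pca
#' @export
tidy.islet_pca <- function(x, ...) {
  tibble(component = seq_along(x$explained_variance),
         explained_variance = x$explained_variance)
}

#' @export
print.islet_metrics <- function(x, ...) {
  cat(sprintf("Classification report (n = %d, threshold = %.2f)\n",
              x$n_test, x$threshold))
  cat(sprintf("  ROC AUC:  %s\n  Accuracy: %s\n",
              format(round(x$roc_auc, 3)), format(round(x$accuracy, 3))))
  print(x$per_class)
  invisible(x)
}

#' @export
print.islet_cv <- function(x, ...) {
  cat(sprintf("Tuned %s model: CV ROC AUC %.3f over %d trial(s)\n",
              x$spec$family, x$best_score, nrow(x$cv_table)))
  cat("  best:", paste(names(x$best_params), unlist(x$best_params),
                       sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0("Synthetic islet cohort config: %d cells ",
                     "(%d beta / %d alpha), seed %d\n"),
              x$n_cells, x$n_beta, x$n_alpha, x$seed))
  invisible(x)
}
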