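audit_reasons <- c("ambiguous-identity", "rearrangement",
                   "focal-plane-mismatch", "shape-change", "duplicate")

#' Manifest-driven dataset cleaning
#'
#' Partitions the assembled feature table into retained and excluded records
#' according to a reason-coded manifest (the audit trail of a manual image
#' review). Duplicate rows (same cell and condition) are dropped from the
#' retained partition. The excluded partition is kept: the stability battery
#' later attempts to classify it.
#'
#' @param data feature tibble with a `cell_id` column.
#' @param manifest tibble with columns `cell_id` and `reason`; every id must
#'   exist in `data`, every reason must be one of `"ambiguous-identity"`,
#'   `"rearrangement"`, `"focal-plane-mismatch"`, `"shape-change"`,
#'   `"duplicate"`. An empty manifest retains everything.
#' @return list of class `cleaning_result`: `retained`, `excluded`,
#'   `manifest`.
#' @export
clean_records <- function(data, manifest) {
  stopifnot(is.data.frame(data), "cell_id" %in% names(data))
  if (is.null(manifest) || nrow(manifest) == 0L) {
    manifest <- tibble(cell_id = character(), reason = character())
  }
  stopifnot(all(c("cell_id", "reason") %in% names(manifest)))
  unknown <- setdiff(manifest$cell_id, data$cell_id)
  if (length(unknown))
    stop("clean_records(): manifest lists unknown cell id(s): ",
         paste(head(unknown, 5), collapse = ", "))
  bad <- setdiff(manifest$reason, audit_reasons)
  if (length(bad))
    stop("clean_records(): unknown reason code(s): ",
         paste(unique(bad), collapse = ", "))
  excluded <- dplyr::filter(data, .data$cell_id %in% manifest$cell_id)
  retained <- dplyr::filter(data, !(.data$cell_id %in% manifest$cell_id))
  key_cols <- intersect(c("cell_id", "condition"), names(retained))
  retained <- dplyr::distinct(retained,
                              dplyr::across(dplyr::all_of(key_cols)),
                              .keep_all = TRUE)
  structure(list(retained = retained, excluded = excluded,
                 manifest = manifest),
            class = "cleaning_result")
}

#' Impute missing feature values with zero
#'
#' Missing values in the feature matrix mark the absence of signal (a cell
#' without lipofuscin granules, an empty pixel population); they are imputed
#' with zeros to retain that meaning. Nothing else is altered.
#'
#' @param data data frame or matrix of features.
#' @return same shape, `NA`/`NaN` replaced by 0.
#' @export
impute_missing <- function(data) {
  if (is.matrix(data)) {
    data[!is.finite(data)] <- 0
    return(data)
  }
  dplyr::mutate(as_tibble(data), dplyr::across(
    dplyr::where(is.numeric),
    function(v) ifelse(is.finite(v), v, 0)))
}

#' Local outlier factor scores
#'
#' Density-based outlier score of Breunig et al.: the ratio of each point's
#' local reachability density to that of its k nearest neighbours. Scores
#' near 1 mark inliers; scores well above 1 mark points in locally sparse
#' regions.
#'
#' @param x numeric matrix or data frame (rows = observations).
#' @param n_neighbors neighbourhood size k (default 20).
#' @return numeric LOF score per row.
#' @export
lof_scores <- function(x, n_neighbors = 20L) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n >= n_neighbors + 1L)
  d <- as.matrix(dist(x))
  diag(d) <- Inf
  k <- n_neighbors
  kdist <- numeric(n)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    di <- d[i, ]
    kd <- sort(di, partial = k)[k]
    kdist[i] <- kd
    nbrs[[i]] <- which(di <= kd)
  }
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    reach <- pmax(kdist[nbrs[[i]]], d[i, nbrs[[i]]])
    lrd[i] <- 1 / max(mean(reach), .Machine$double.eps)
  }
  vapply(seq_len(n), function(i) mean(lrd[nbrs[[i]]]) / lrd[i], 0)
}

#' Replace LOF-flagged outlier rows by feature means
#'
#' Rows whose local outlier factor exceeds `lof_threshold` (1.5, matching
#' the usual automatic contamination rule) have all their feature values
#' replaced by the per-feature mean over inlier rows. Non-flagged values are
#' untouched; matrix shape is preserved. With fewer than `n_neighbors + 1`
#' rows the step is skipped with a warning.
#'
#' @param data numeric data frame or matrix.
#' @param n_neighbors LOF neighbourhood size.
#' @param lof_threshold flagging threshold.
#' @return list: `data` (same shape), `flagged` (logical per row),
#'   `column_means` (inlier means used for substitution).
#' @export
replace_outliers <- function(data, n_neighbors = 20L, lof_threshold = 1.5) {
  x <- as.matrix(data)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (nrow(x) < n_neighbors + 1L) {
    warning("replace_outliers(): too few rows, step skipped")
    return(list(data = as_tibble(x), flagged = rep(FALSE, nrow(x)),
                column_means = colMeans(x)))
  }
  scores <- lof_scores(x, n_neighbors)
  flagged <- scores > lof_threshold
  means <- colMeans(x[!flagged, , drop = FALSE])
  if (any(flagged)) x[flagged, ] <- matrix(means, sum(flagged), ncol(x),
                                           byrow = TRUE)
  list(data = as_tibble(x), flagged = flagged, column_means = means)
}

#' Fit / apply the min-max scaling state
#'
#' `fit_preprocess()` records per-feature minima and maxima (to be fitted on
#' the training partition only); `apply_preprocess()` maps
#' `x' = (x - min) / (max - min)`. Features that are constant in the fitted
#' data map to 0; values outside the fitted range (possible on test data)
#' are not clipped.
#'
#' @param data numeric data frame or matrix (fit) / data to transform
#'   (apply).
#' @param state a `preprocess_state` from `fit_preprocess()`.
#' @param fitted_on optional label recording which partition the state was
#'   fitted on.
#' @return `fit_preprocess()`: list of class `preprocess_state` (`min`,
#'   `max`, `fitted_on`). `apply_preprocess()`: transformed tibble.
#' @export
fit_preprocess <- function(data, fitted_on = "train") {
  x <- as.matrix(data)
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max),
                 features = colnames(x), fitted_on = fitted_on),
            class = "preprocess_state")
}

#' @rdname fit_preprocess
#' @export
apply_preprocess <- function(state, data) {
  stopifnot(inherits(state, "preprocess_state"))
  x <- as.matrix(data)
  missing_feats <- setdiff(state$features, colnames(x))
  if (length(missing_feats))
    stop("apply_preprocess(): data lacks fitted feature(s): ",
         paste(head(missing_feats, 5), collapse = ", "))
  x <- x[, state$features, drop = FALSE]
  rng <- state$max - state$min
  scaled <- sweep(x, 2, state$min)
  scaled <- sweep(scaled, 2, ifelse(rng > 0, rng, 1), "/")
  scaled[, rng == 0] <- 0
  as_tibble(scaled)
}

#' Stratified train/test split
#'
#' Draws `round(test_fraction * n)` test rows per class, preserving class
#' proportions within one unit per class. Seeded and disjoint.
#'
#' @param labels class label per row.
#' @param test_fraction held-out fraction (default 0.25).
#' @param seed integer seed.
#' @return list: `train` and `test` integer row indices.
#' @export
split_stratified <- function(labels, test_fraction = 0.25, seed = 1L) {
  labels <- as.factor(labels)
  stopifnot(all(table(labels) >= 2L))
  set.seed(seed)
  test_idx <- unlist(lapply(levels(labels), function(lv) {
    rows <- which(labels == lv)
    sample(rows, round(length(rows) * test_fraction))
  }), use.names = FALSE)
  test_idx <- sort(test_idx)
  list(train = setdiff(seq_along(labels), test_idx), test = test_idx)
}

#' SMOTE minority oversampling
#'
#' Synthetic Minority Oversampling Technique: synthetic minority rows are
#' convex combinations \eqn{x + u (x_{nn} - x)}, `u ~ U(0, 1)`, between a
#' minority point and one of its `k_neighbors` nearest minority neighbours,
#' generated until the class counts are exactly equal. Original rows are
#' returned first and bit-identical.
#'
#' @param data numeric data frame or matrix of features.
#' @param labels two-level factor aligned with `data`.
#' @param k_neighbors neighbourhood size (default 5); reduced with a warning
#'   if the minority class is too small.
#' @param seed integer seed.
#' @return list: `data` (tibble, original rows then synthetic rows),
#'   `labels` (factor), `n_synthetic`.
#' @export
rebalance_smote <- function(data, labels, k_neighbors = 5L, seed = 1L) {
  x <- as.matrix(data)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  labels <- as.factor(labels)
  stopifnot(nlevels(droplevels(labels)) == 2L, nrow(x) == length(labels))
  counts <- table(labels)
  counts <- counts[counts > 0]
  if (length(unique(counts)) == 1L)
    return(list(data = as_tibble(x), labels = labels, n_synthetic = 0L))
  minority <- names(which.min(counts))
  need <- max(counts) - min(counts)
  min_rows <- which(labels == minority)
  if (length(min_rows) <= k_neighbors) {
    warning("rebalance_smote(): minority class has ", length(min_rows),
            " rows; reducing k_neighbors to ", length(min_rows) - 1L)
    k_neighbors <- length(min_rows) - 1L
  }
  stopifnot(k_neighbors >= 1L)
  xm <- x[min_rows, , drop = FALSE]
  dm <- as.matrix(dist(xm))
  diag(dm) <- Inf
  nn <- matrix(apply(dm, 1, function(dr) order(dr)[seq_len(k_neighbors)]),
               ncol = nrow(xm))
  nn <- t(nn)
  set.seed(seed)
  base <- sample(seq_len(nrow(xm)), need, replace = TRUE)
  pick <- nn[cbind(base, sample(seq_len(k_neighbors), need, replace = TRUE))]
  u <- runif(need)
  synth <- xm[base, , drop = FALSE] +
    u * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
  out <- rbind(x, synth)
  list(data = as_tibble(out),
       labels = factor(c(as.character(labels),
                         rep(minority, need)), levels = levels(labels)),
       n_synthetic = as.integer(need))
}

#' One-hot encode donor identity
#'
#' Optional categorical encoding: appends one indicator column per donor.
#' The glucose condition is already numerically encoded in the schema
#' feature `exp_glucose`.
#'
#' @param data feature tibble with a `donor_id` column.
#' @return tibble with appended `donor_<id>` 0/1 columns.
#' @export
encode_donor_onehot <- function(data) {
  stopifnot("donor_id" %in% names(data))
  for (d in sort(unique(data$donor_id)))
    data[[paste0("donor_", d)]] <- as.numeric(data$donor_id == d)
  data
}

#' The full preprocessing chain
#'
#' Fixed order: zero imputation, stratified split, LOF outlier replacement
#' (fitted and applied on the training partition), min-max scaling (state
#' fitted on the training partition, applied to both), SMOTE rebalancing of
#' the training partition only. No test row influences any fitted statistic.
#' `paper_faithful = TRUE` instead fits the outlier and scaling steps on the
#' full matrix and applies SMOTE to the whole dataset before splitting,
#' replicating the prose description of the original study.
#'
#' @param data feature tibble with a `cell_type` column.
#' @param test_fraction held-out fraction.
#' @param seed integer seed (stage seeds are derived from it).
#' @param smote apply SMOTE (default TRUE).
#' @param k_neighbors SMOTE neighbourhood size.
#' @param lof_neighbors LOF neighbourhood size.
#' @param paper_faithful see Description.
#' @return list of class `preprocess_result`: `train` (`x` tibble, `y`
#'   factor), `test` (`x`, `y`), `state` (`preprocess_state`), `split` (row
#'   indices), `outliers` (flags and substitution means), `n_synthetic`.
#' @export
preprocess_split <- function(data, test_fraction = 0.25, seed = 1L,
                             smote = TRUE, k_neighbors = 5L,
                             lof_neighbors = 20L, paper_faithful = FALSE) {
  stopifnot("cell_type" %in% names(data))
  feats <- feature_columns(data)
  y <- factor(data$cell_type, levels = c("alpha", "beta"))
  x <- impute_missing(data[, feats])
  if (paper_faithful) {
    out <- replace_outliers(x, n_neighbors = lof_neighbors)
    state <- fit_preprocess(out$data, fitted_on = "full")
    xs <- apply_preprocess(state, out$data)
    if (smote) {
      sm <- rebalance_smote(xs, y, k_neighbors,
                            seed = derive_seed(seed, "smote"))
      xs <- sm$data; y <- sm$labels
      n_syn <- sm$n_synthetic
    } else n_syn <- 0L
    idx <- split_stratified(y, test_fraction, derive_seed(seed, "split"))
    return(structure(list(
      train = list(x = xs[idx$train, ], y = y[idx$train]),
      test = list(x = xs[idx$test, ], y = y[idx$test]),
      state = state, split = idx, outliers = out[c("flagged", "column_means")],
      n_synthetic = n_syn), class = "preprocess_result"))
  }
  idx <- split_stratified(y, test_fraction, derive_seed(seed, "split"))
  x_train <- x[idx$train, ]
  x_test <- x[idx$test, ]
  out <- replace_outliers(x_train, n_neighbors = lof_neighbors)
  x_train <- out$data
  state <- fit_preprocess(x_train, fitted_on = "train")
  x_train <- apply_preprocess(state, x_train)
  x_test <- apply_preprocess(state, x_test)
  y_train <- y[idx$train]
  n_syn <- 0L
  if (smote) {
    sm <- rebalance_smote(x_train, y_train, k_neighbors,
                          seed = derive_seed(seed, "smote"))
    x_train <- sm$data
    y_train <- sm$labels
    n_syn <- sm$n_synthetic
  }
  structure(list(
    train = list(x = x_train, y = y_train),
    test = list(x = x_test, y = y[idx$test]),
    state = state, split = idx,
    outliers = out[c("flagged", "column_means")],
    n_synthetic = n_syn), class = "preprocess_result")
}
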