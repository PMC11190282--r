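#' PCA embedding of a preprocessed feature matrix
#'
#' Mean-centered principal component analysis. Component signs are fixed by
#' the largest-loading-positive convention, so the embedding is fully
#' deterministic.
#'
#' @param data data frame of numeric features (already imputed and scaled),
#'   or a numeric matrix.
#' @param k number of components to keep (`<= n_features`).
#' @return list of class `islet_pca`: `coordinates` (tibble, `PC1..PCk`),
#'   `explained_variance` (fraction per kept component, non-increasing),
#'   `cum_explained` (over all components), `loadings`.
#' @export
pca_embed <- function(data, k = 2L) {
  x <- as.matrix(data)
  stopifnot(is.numeric(x), k >= 1L)
  if (k > ncol(x)) stop("pca_embed(): k exceeds the number of features")
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  if (k > length(p$sdev)) stop("pca_embed(): k exceeds the matrix rank")
  # sign convention: the loading of largest magnitude is positive
  for (j in seq_len(ncol(p$rotation))) {
    lead <- which.max(abs(p$rotation[, j]))
    if (p$rotation[lead, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  ev <- p$sdev^2 / sum(p$sdev^2)
  coords <- as_tibble(p$x[, seq_len(k), drop = FALSE])
  structure(list(coordinates = coords,
                 explained_variance = ev[seq_len(k)],
                 cum_explained = cumsum(ev),
                 loadings = p$rotation[, seq_len(k), drop = FALSE]),
            class = "islet_pca")
}

#' Normalized within-cluster sum of squares
#'
#' \deqn{\mathrm{WCSS} = \frac{1}{N} \sum_i \| x_i - c_{a(i)} \|^2,} the mean
#' squared distance of every point to its own cluster centroid.
#'
#' @param points numeric matrix (N x d).
#' @param assignments integer cluster id per point (1..k).
#' @param centroids numeric matrix (k x d).
#' @return single non-negative number. Empty clusters contribute nothing and
#'   raise a warning.
#' @export
wcss <- function(points, assignments, centroids) {
  points <- as.matrix(points)
  centroids <- as.matrix(centroids)
  stopifnot(length(assignments) == nrow(points),
            all(assignments >= 1), all(assignments <= nrow(centroids)))
  if (length(setdiff(seq_len(nrow(centroids)), unique(assignments))))
    warning("wcss(): empty cluster(s) contribute 0")
  sum((points - centroids[assignments, , drop = FALSE])^2) / nrow(points)
}

# k-means++ seeding (Arthur & Vassilvitskii): spread initial centers by
# sampling proportionally to squared distance from the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (sum(d2) <= 0) idx <- sample.int(n, 1L)
    else idx <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

#' k-means with k-means++ seeding and restarts
#'
#' @param points numeric matrix or data frame.
#' @param k number of clusters.
#' @param n_restarts best-of restarts (default 10).
#' @param seed integer seed (RNG is set inside; fixed seed = fixed result).
#' @return list of class `islet_kmeans`: `assignments`, `centroids`, `wcss`.
#' @export
kmeans_cluster <- function(points, k, n_restarts = 10L, seed = 1L) {
  x <- as.matrix(points)
  stopifnot(k >= 1L, k <= nrow(x))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- suppressWarnings(
      kmeans(x, centers = kmeanspp_centers(x, k), iter.max = 100L,
             algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  structure(list(assignments = best$cluster, centroids = best$centers,
                 wcss = wcss(x, best$cluster, best$centers)),
            class = "islet_kmeans")
}

#' Elbow scan over the number of k-means clusters
#'
#' Runs seeded k-means for each `k` in `[k_min, k_max]`, records the
#' normalized WCSS, and locates the knee as the point of maximum discrete
#' curvature of the axis-normalized WCSS curve (second differences of the
#' curve rescaled to the unit square — the visual elbow). A knee whose
#' curvature barely exceeds the curve's typical variation is flagged low
#' confidence.
#'
#' @param points numeric matrix or data frame (e.g. a PCA embedding).
#' @param k_min,k_max scan range (defaults 2 and 59; `k_max < N`).
#' @param n_restarts,seed forwarded to [kmeans_cluster()].
#' @return list of class `islet_elbow`: `curve` (tibble `k`, `wcss`),
#'   `knee_k`, `curvature`, `low_confidence`.
#' @export
elbow_scan <- function(points, k_min = 2L, k_max = 59L, n_restarts = 10L,
                       seed = 1L) {
  x <- as.matrix(points)
  stopifnot(k_min >= 1L, k_max > k_min, k_max < nrow(x))
  ks <- seq.int(k_min, k_max)
  ws <- vapply(ks, function(k)
    kmeans_cluster(x, k, n_restarts, seed = derive_seed(seed, paste0("k", k)))$wcss,
    0)
  if (length(ks) > 2L) {
    # discrete maximum curvature of the normalized curve: both axes are
    # scaled to [0, 1] (the visual elbow), then kappa = |y''| / (1 + y'^2)^1.5
    # from central differences; the raw second difference is dominated by the
    # large WCSS drops at small k regardless of where the elbow sits
    xs <- (ks - ks[1]) / (ks[length(ks)] - ks[1])
    ys <- (ws - min(ws)) / max(max(ws) - min(ws), .Machine$double.eps)
    h <- xs[2] - xs[1]
    i <- seq_len(length(ys) - 2L)
    d1 <- (ys[i + 2L] - ys[i]) / (2 * h)
    d2 <- (ys[i] - 2 * ys[i + 1L] + ys[i + 2L]) / h^2
    curv <- abs(d2) / (1 + d1^2)^1.5
    knee_i <- which.max(curv) + 1L
    knee <- ks[knee_i]
    low_conf <- max(curv) < 2 * stats::median(curv)
  } else {
    curv <- numeric(0); knee <- ks[which.min(ws)]; low_conf <- TRUE
  }
  structure(list(curve = tibble(k = ks, wcss = ws), knee_k = knee,
                 curvature = curv, low_confidence = low_conf),
            class = "islet_elbow")
}

#' Gini impurity of labelled clusters
#'
#' Per-cluster impurity \eqn{G(j) = 1 - \sum_k (n_{k,j}/n_j)^2} and its
#' unweighted average over clusters. A cluster holding a single class scores
#' 0; a 50/50 two-class cluster scores 0.5.
#'
#' @param assignments cluster id per point.
#' @param labels class label per point (factor or character).
#' @return list of class `islet_gini`: `per_cluster` (tibble `cluster`, `n`,
#'   `gini`), `mean_gini` (unweighted over non-empty clusters).
#' @export
gini_report <- function(assignments, labels) {
  stopifnot(length(assignments) == length(labels), !anyNA(labels))
  tab <- table(assignments, labels)
  props <- tab / rowSums(tab)
  gini <- 1 - rowSums(props^2)
  per <- tibble(cluster = rownames(tab), n = as.integer(rowSums(tab)),
                gini = as.numeric(gini))
  if (any(per$n == 0L)) {
    warning("gini_report(): empty cluster(s) excluded from the average")
    per <- per[per$n > 0L, ]
  }
  structure(list(per_cluster = per, mean_gini = mean(per$gini)),
            class = "islet_gini")
}

#' ROC AUC of a two-cluster k-means baseline
#'
#' Fits k-means with `k` clusters on the embedding, scores every point by
#' its cluster's beta fraction, and reports the ROC AUC of that score
#' against the true labels. The score is invariant to which cluster is
#' called "beta". A degenerate single-occupied-cluster outcome returns 0.5
#' with a warning.
#'
#' @param embedding numeric matrix or data frame (e.g. PCA coordinates).
#' @param labels factor with levels `alpha`, `beta` (beta = positive class).
#' @param k number of clusters (default 2).
#' @param n_restarts,seed forwarded to [kmeans_cluster()].
#' @return list of class `islet_cluster_auc`: `roc_auc`, `cluster_scores`
#'   (tibble), `assignments`.
#' @export
cluster_auc <- function(embedding, labels, k = 2L, n_restarts = 10L,
                        seed = 1L) {
  labels <- factor(labels, levels = c("alpha", "beta"))
  stopifnot(nlevels(droplevels(labels)) == 2L)
  km <- kmeans_cluster(embedding, k, n_restarts, seed)
  frac <- tapply(labels == "beta", km$assignments, mean)
  score <- as.numeric(frac[as.character(km$assignments)])
  if (length(unique(km$assignments)) < 2L || length(unique(score)) < 2L) {
    warning("cluster_auc(): degenerate clustering, AUC set to 0.5")
    auc <- 0.5
  } else {
    auc <- as.numeric(pROC::auc(pROC::roc(labels, score, quiet = TRUE,
                                          levels = c("alpha", "beta"),
                                          direction = "<")))
  }
  structure(list(roc_auc = auc,
                 cluster_scores = tibble(cluster = names(frac),
                                         beta_fraction = as.numeric(frac)),
                 assignments = km$assignments),
            class = "islet_cluster_auc")
}

#' Exploratory analysis report
#'
#' Convenience wrapper running the full exploratory battery on an assembled
#' feature table: zero imputation + min-max scaling, PCA, elbow scan on the
#' 2-D embedding, Gini impurity of the knee clustering, and the two-cluster
#' ROC AUC baseline.
#'
#' @param data feature tibble with a `cell_type` column (see
#'   [generate_feature_matrix()]).
#' @param k_max elbow scan upper bound.
#' @param seed integer seed.
#' @return list of class `islet_explore` with elements `pca`, `elbow`,
#'   `gini`, `cluster_auc`.
#' @export
explore_features <- function(data, k_max = 30L, seed = 1L) {
  feats <- feature_columns(data)
  x <- impute_missing(data[, feats])
  state <- fit_preprocess(x)
  x <- as.matrix(apply_preprocess(state, x))
  pca <- pca_embed(x, k = 2L)
  emb <- as.matrix(pca$coordinates)
  elbow <- elbow_scan(emb, k_max = min(k_max, nrow(emb) - 1L),
                      seed = derive_seed(seed, "elbow"))
  km <- kmeans_cluster(emb, elbow$knee_k, seed = derive_seed(seed, "gini"))
  gini <- gini_report(km$assignments, data$cell_type)
  cauc <- cluster_auc(emb, data$cell_type, seed = derive_seed(seed, "auc"))
  structure(list(pca = pca, elbow = elbow, gini = gini, cluster_auc = cauc),
            class = "islet_explore")
}
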