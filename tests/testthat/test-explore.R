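# Well-separated Gaussian blobs on a grid.
make_blobs <- function(k, n_per = 30, sd = 0.05, seed = 1) {
  set.seed(seed)
  centers <- cbind(rep(seq_len(ceiling(sqrt(k))), length.out = k),
                   rep(seq_len(ceiling(sqrt(k))), each = ceiling(sqrt(k)))[seq_len(k)])
  x <- do.call(rbind, lapply(seq_len(k), function(j)
    cbind(rnorm(n_per, centers[j, 1], sd), rnorm(n_per, centers[j, 2], sd))))
  list(x = x, assignment = rep(seq_len(k), each = n_per), centers = centers)
}

test_that("pca_embed recovers the dominant axis deterministically", {
  set.seed(4)
  t_par <- rnorm(100, sd = 3)
  x <- cbind(t_par + rnorm(100, sd = 0.1), -t_par + rnorm(100, sd = 0.1),
             rnorm(100, sd = 0.1))
  p <- pca_embed(x, k = 2)
  expect_s3_class(p, "islet_pca")
  expect_gt(p$explained_variance[1], 0.95)
  expect_equal(sum(p$cum_explained[length(p$cum_explained)]), 1)
  # sign convention: the largest-magnitude loading of each PC is positive
  for (j in 1:2) expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  expect_equal(pca_embed(x, k = 2)$coordinates, p$coordinates)
  expect_error(pca_embed(x, k = 5), "exceeds")
})

test_that("wcss matches the paper definition and a brute-force loop", {
  # two points 0 and 2 in one cluster with centroid 1: mean squared dist = 1
  expect_equal(wcss(matrix(c(0, 2)), c(1L, 1L), matrix(1)), 1)
  set.seed(8)
  x <- matrix(rnorm(50 * 3), 50)
  a <- sample(1:4, 50, replace = TRUE)
  cen <- matrix(rnorm(4 * 3), 4)
  brute <- 0
  for (i in 1:50) for (d in 1:3) brute <- brute + (x[i, d] - cen[a[i], d])^2
  expect_equal(wcss(x, a, cen), brute / 50)
  expect_warning(wcss(matrix(c(0, 2)), c(1L, 1L), matrix(c(1, 5))), "empty")
})

test_that("kmeans_cluster separates obvious blobs reproducibly", {
  b <- make_blobs(2, n_per = 25, seed = 2)
  km <- kmeans_cluster(b$x, k = 2, seed = 9)
  expect_s3_class(km, "islet_kmeans")
  # the found partition equals the generative one up to label swap
  tab <- table(km$assignments, b$assignment)
  expect_true(all(apply(tab, 1, max) == 25L))
  expect_equal(kmeans_cluster(b$x, k = 2, seed = 9)$assignments,
               km$assignments)
  expect_equal(km$wcss, wcss(b$x, km$assignments, km$centroids))
})

test_that("elbow_scan finds the knee of a small blob problem", {
  b <- make_blobs(3, n_per = 25, sd = 0.04, seed = 5)
  el <- elbow_scan(b$x, k_min = 2, k_max = 8, seed = 3)
  expect_s3_class(el, "islet_elbow")
  expect_equal(nrow(el$curve), 7L)
  expect_true(el$knee_k %in% 2:4)
  expect_false(el$low_confidence)
})

test_that("gini_report matches hand values and a brute-force loop", {
  # 3 beta + 1 alpha: 1 - (9/16 + 1/16) = 0.375
  g <- gini_report(rep(1L, 4), c("beta", "beta", "beta", "alpha"))
  expect_equal(g$mean_gini, 0.375)
  # pure cluster scores exactly 0
  expect_equal(gini_report(rep(1L, 20), rep("beta", 20))$mean_gini, 0)
  set.seed(10)
  a <- sample(1:3, 40, replace = TRUE)
  lab <- sample(c("alpha", "beta"), 40, replace = TRUE)
  rep_g <- gini_report(a, lab)
  brute <- vapply(sort(unique(a)), function(j) {
    p <- table(lab[a == j]) / sum(a == j)
    1 - sum(p^2)
  }, 0)
  expect_equal(rep_g$per_cluster$gini, unname(brute))
  expect_equal(rep_g$mean_gini, mean(brute))
})

test_that("cluster_auc scores separable labels highly, invariant to naming", {
  b <- make_blobs(2, n_per = 30, seed = 6)
  labels <- factor(rep(c("alpha", "beta"), each = 30),
                   levels = c("alpha", "beta"))
  ca <- cluster_auc(b$x, labels, seed = 4)
  expect_s3_class(ca, "islet_cluster_auc")
  expect_gt(ca$roc_auc, 0.95)
  # flipping the label-to-blob pairing cannot change the score
  ca_fl <- cluster_auc(b$x, factor(rev(as.character(labels)),
                                   levels = c("alpha", "beta")), seed = 4)
  expect_equal(ca_fl$roc_auc, ca$roc_auc)
})

test_that("explore_features runs the whole battery on a synthetic matrix", {
  ex <- explore_features(fx_fm_small(), k_max = 6, seed = 2)
  expect_s3_class(ex, "islet_explore")
  expect_s3_class(ex$pca, "islet_pca")
  expect_s3_class(ex$elbow, "islet_elbow")
  expect_s3_class(ex$gini, "islet_gini")
  expect_true(ex$gini$mean_gini >= 0 && ex$gini$mean_gini <= 0.5)
  expect_true(ex$cluster_auc$roc_auc >= 0 && ex$cluster_auc$roc_auc <= 1)
})
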