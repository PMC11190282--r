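#' Plot the k-means elbow curve
#'
#' WCSS against the number of clusters with the detected knee highlighted.
#'
#' @param elbow an `islet_elbow` from [elbow_scan()].
#' @return a ggplot object.
#' @export
plot_elbow <- function(elbow) {
  knee <- dplyr::filter(elbow$curve, .data$k == elbow$knee_k)
  ggplot2::ggplot(elbow$curve, ggplot2::aes(.data$k, .data$wcss)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_point(data = knee, colour = "red", size = 3) +
    ggplot2::labs(x = "number of clusters k", y = "WCSS (mean within-cluster SS)",
                  title = sprintf("Elbow scan (knee at k = %d)", elbow$knee_k)) +
    ggplot2::theme_minimal()
}

#' Plot a feature-importance ranking
#'
#' @param ranking an `islet_importance` from [importance_ranking()].
#' @param top_n number of top features to show (default 9).
#' @return a ggplot object.
#' @export
plot_importance <- function(ranking, top_n = 9L) {
  d <- head(ranking, top_n)
  ggplot2::ggplot(d, ggplot2::aes(.data$importance,
                                  stats::reorder(.data$feature,
                                                 .data$importance))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "normalized gain importance", y = NULL,
                  title = sprintf("Top %d features", nrow(d))) +
    ggplot2::theme_minimal()
}

#' PCA embedding scatter plot
#'
#' @param object an `islet_pca` from [pca_embed()].
#' @param labels optional per-row class labels for colouring.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot islet_pca
#' @export
autoplot.islet_pca <- function(object, labels = NULL, ...) {
  d <- object$coordinates
  ev <- object$explained_variance
  p <- if (is.null(labels)) {
    ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2)) +
      ggplot2::geom_point(alpha = 0.5, size = 0.8)
  } else {
    d$cell_type <- labels
    ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2,
                                    colour = .data$cell_type)) +
      ggplot2::geom_point(alpha = 0.5, size = 0.8)
  }
  p + ggplot2::labs(
    x = sprintf("PC1 (%.0f%%)", 100 * ev[1]),
    y = sprintf("PC2 (%.0f%%)", 100 * ev[2])) +
    ggplot2::theme_minimal()
}

#' Phasor-plot view of a cell bundle
#'
#' Per-pixel (g, s) density of one cell with the universal semicircle and
#' the mono-exponential free/bound NAD(P)H reference points.
#'
#' @param bundle a [cell_bundle()].
#' @param tau_free,tau_bound reference lifetimes (ns).
#' @param rep_rate repetition rate (MHz).
#' @return a ggplot object.
#' @export
plot_phasor <- function(bundle, tau_free = 0.4, tau_bound = 3.4,
                        rep_rate = 80) {
  inside <- bundle$roi_mask > 0
  d <- tibble(g = bundle$g_map[inside], s = bundle$s_map[inside])
  d <- d[is.finite(d$g) & is.finite(d$s), ]
  semi <- tibble(g = seq(0, 1, length.out = 200))
  semi$s <- sqrt(pmax(0.25 - (semi$g - 0.5)^2, 0))
  refs <- phasor_of_lifetime(c(tau_free, tau_bound), rep_rate)
  ggplot2::ggplot(d, ggplot2::aes(.data$g, .data$s)) +
    ggplot2::geom_bin2d(bins = 60) +
    ggplot2::geom_path(data = semi, colour = "grey30", linetype = 2) +
    ggplot2::geom_point(data = refs, colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste("Phasor plot, cell", bundle$cell_id),
                  fill = "pixels") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
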