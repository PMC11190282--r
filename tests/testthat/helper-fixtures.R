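# Shared fixtures, computed once per test run and cached so the expensive
# synthetic cohorts are generated a single time across test files.
.fx <- new.env(parent = emptyenv())

fx_cached <- function(name, make) {
  if (is.null(.fx[[name]])) .fx[[name]] <- make()
  .fx[[name]]
}

# Small full-raster cohort (decay synthesis), for bundle-level tests.
fx_cohort_small <- function() {
  fx_cached("cohort_small", function()
    generate_cohort(synth_config(n_cells = 6, image_size = 64,
                                 cell_radius = 12, seed = 42),
                    method = "decay"))
}

# Small feature matrix (analytic path, default per-condition layout).
fx_fm_small <- function() {
  fx_cached("fm_small", function()
    generate_feature_matrix(synth_config(n_cells = 40, image_size = 96,
                                         seed = 7)))
}

# The parameter-recovery cohort: 900 cells, one row per cell, defaults
# (twofold lipofuscin effect, beta-specific metabolic shift). Seed fixed
# a priori.
fx_fm900 <- function() {
  fx_cached("fm900", function()
    generate_feature_matrix(synth_config(n_cells = 900, image_size = 128,
                                         layout = "per_cell",
                                         seed = 20240901)))
}

# Two-class Gaussian toy data for classifier tests: class means separated
# by `sep` along every coordinate.
fx_gauss <- function(n_alpha = 30, n_beta = 30, d = 4, sep = 2, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_alpha * d), n_alpha),
             matrix(rnorm(n_beta * d, mean = sep / sqrt(d)), n_beta))
  colnames(x) <- paste0("f", seq_len(d))
  list(x = x,
       y = factor(rep(c("alpha", "beta"), c(n_alpha, n_beta)),
                  levels = c("alpha", "beta")))
}

# Rasterized disk mask of radius r centered in a (2r + 2*margin)^2 image.
fx_disk_mask <- function(r = 50, margin = 6) {
  L <- 2 * r + 2 * margin
  c0 <- (L + 1) / 2
  xs <- seq_len(L) - c0
  (outer(xs^2, xs^2, `+`) <= r^2) * 1L
}
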