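#' Configuration of the synthetic islet generator
#'
#' Defines the statistical structure of a synthetic cohort of islet cells:
#' a ~2:1 beta:alpha composition, twofold higher lipofuscin content in beta
#' cells, two-component free/bound NAD(P)H phasor mixtures, and a
#' glucose-induced shift toward the bound (oxidative) pole that is stronger
#' in beta cells. Defaults emulate the study conditions the analysis assumes
#' (966 cells, beta fraction 2/3, 0.4/3.4 ns lifetimes at 80 MHz).
#'
#' @param n_cells number of cells (each gets a 2.2 mM and a 16.7 mM bundle).
#' @param beta_fraction fraction of beta cells, in (0, 1).
#' @param lipofuscin_ratio_beta_alpha beta/alpha ratio of mean granule count.
#' @param lipofuscin_mean_alpha mean granule count per alpha cell (Poisson).
#' @param tau_free,tau_bound free / bound NAD(P)H lifetimes (ns).
#' @param lipo_tau lipofuscin mono-exponential lifetime (ns).
#' @param lipo_weight lipofuscin photon fraction inside granule pixels.
#' @param bound_fraction_low_glucose named numeric `c(alpha=, beta=)`: bound
#'   NAD(P)H photon fraction at 2.2 mM glucose.
#' @param bound_fraction_shift named numeric `c(alpha=, beta=)`: increment at
#'   16.7 mM (beta > alpha encodes the beta-specific oxidative shift).
#' @param bound_fraction_shift_sd per-cell s.d. of the glucose-induced shift
#'   (cell-level metabolic response heterogeneity; the default 0.04 against a
#'   0.08 class gap makes the shift informative but not perfectly separating).
#' @param bound_fraction_jitter per-cell s.d. of the bound fraction.
#' @param rep_rate laser repetition rate (MHz).
#' @param n_bins decay histogram bins over one laser period.
#' @param image_size bundle raster size in pixels.
#' @param cell_radius mean cell radius (px).
#' @param cell_radius_sdlog lognormal s.d. of per-cell radius.
#' @param shape_perturbation star-convex vertex radius perturbation (<= 0.2
#'   gives realistic circularity spread).
#' @param granule_radius length-2 range of granule radii (px).
#' @param granule_amp granule brightness multiplier over the cell base.
#' @param intensity_params list with `alpha` and `beta` elements, each
#'   `c(meanlog=, sdlog=)` of the lognormal per-cell photon rate (photons
#'   per pixel).
#' @param texture_sdlog per-pixel lognormal intensity texture s.d.
#' @param poisson logical: apply photon shot noise.
#' @param gaussian_sd detector read-noise s.d. added to the intensity image.
#' @param donor_params list of length-2 ranges `age`, `bmi`, `si` and count
#'   `n_donors`; defaults span the study's four donors (age 46-85, BMI
#'   23.0-27.7) and a typical stimulation-index range.
#' @param layout feature-matrix row layout, see [build_feature_matrix()].
#' @param seed integer seed; a fixed seed makes cohorts bit-identical.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(n_cells = 966,
                         beta_fraction = 2 / 3,
                         lipofuscin_ratio_beta_alpha = 2,
                         lipofuscin_mean_alpha = 2,
                         tau_free = 0.4, tau_bound = 3.4,
                         lipo_tau = 1.5, lipo_weight = 0.75,
                         bound_fraction_low_glucose = c(alpha = 0.30, beta = 0.35),
                         bound_fraction_shift = c(alpha = 0.02, beta = 0.10),
                         bound_fraction_shift_sd = 0.04,
                         bound_fraction_jitter = 0.02,
                         rep_rate = 80, n_bins = 256L,
                         image_size = 512L,
                         cell_radius = 24, cell_radius_sdlog = 0.12,
                         shape_perturbation = 0.2,
                         granule_radius = c(2, 4), granule_amp = 4,
                         intensity_params = list(
                           alpha = c(meanlog = log(350), sdlog = 0.25),
                           beta = c(meanlog = log(450), sdlog = 0.25)),
                         texture_sdlog = 0.2,
                         poisson = TRUE, gaussian_sd = 0,
                         donor_params = list(n_donors = 4, age = c(46, 85),
                                             bmi = c(23.0, 27.7),
                                             si = c(1.5, 4.0)),
                         layout = c("per_condition", "per_cell"),
                         seed = 1L) {
  layout <- match.arg(layout)
  stopifnot(n_cells >= 4, beta_fraction > 0, beta_fraction < 1,
            tau_free < tau_bound, lipofuscin_ratio_beta_alpha > 0,
            all(c("alpha", "beta") %in% names(bound_fraction_low_glucose)),
            all(c("alpha", "beta") %in% names(bound_fraction_shift)),
            all(bound_fraction_low_glucose >= 0),
            all(bound_fraction_shift >= 0), bound_fraction_shift_sd >= 0,
            all(bound_fraction_low_glucose + bound_fraction_shift <= 1),
            shape_perturbation >= 0, shape_perturbation < 1,
            length(granule_radius) == 2, granule_radius[1] <= granule_radius[2])
  n_beta <- round(n_cells * beta_fraction)
  n_alpha <- n_cells - n_beta
  if (n_beta < 2 || n_alpha < 2)
    stop("synth_config(): need at least 2 cells per class, got ",
         n_alpha, " alpha / ", n_beta, " beta")
  max_r <- cell_radius * exp(2.5 * cell_radius_sdlog) * (1 + shape_perturbation)
  if (max_r + 4 >= image_size / 2)
    stop("synth_config(): image_size ", image_size,
         " too small to place cells of radius ~", round(cell_radius))
  cfg <- as.list(environment())
  cfg$n_beta <- n_beta
  cfg$n_alpha <- n_alpha
  structure(cfg, class = "synth_config")
}

# --- per-cell truth ---------------------------------------------------------

sample_donor_table <- function(config) {
  dp <- config$donor_params
  tibble(
    donor_id = sprintf("D%02d", seq_len(dp$n_donors)),
    age = round(runif(dp$n_donors, dp$age[1], dp$age[2])),
    bmi = round(runif(dp$n_donors, dp$bmi[1], dp$bmi[2]), 2),
    si = round(runif(dp$n_donors, dp$si[1], dp$si[2]), 2)
  )
}

sample_truth <- function(config, donors) {
  n <- config$n_cells
  type <- rep(c("beta", "alpha"), c(config$n_beta, config$n_alpha))
  type <- sample(type)
  donor_id <- sample(donors$donor_id, n, replace = TRUE)
  islet_id <- paste0(donor_id, "-I", 1 + (seq_len(n) %% 4))
  lam <- ifelse(type == "beta",
                config$lipofuscin_mean_alpha * config$lipofuscin_ratio_beta_alpha,
                config$lipofuscin_mean_alpha)
  ip <- config$intensity_params
  meanlog <- ifelse(type == "beta", ip$beta["meanlog"], ip$alpha["meanlog"])
  sdlog <- ifelse(type == "beta", ip$beta["sdlog"], ip$alpha["sdlog"])
  fb_low <- config$bound_fraction_low_glucose[type] +
    rnorm(n, 0, config$bound_fraction_jitter)
  fb_high <- fb_low + config$bound_fraction_shift[type] +
    rnorm(n, 0, config$bound_fraction_shift_sd)
  tibble(
    cell_id = sprintf("C%04d", seq_len(n)),
    islet_id = islet_id, donor_id = donor_id, type = type,
    radius = config$cell_radius * rlnorm(n, 0, config$cell_radius_sdlog),
    base_intensity = rlnorm(n, meanlog, sdlog),
    n_granules = rpois(n, lam),
    f_bound_low = pmin(pmax(fb_low, 0.02), 0.95),
    f_bound_high = pmin(pmax(fb_high, 0.02), 0.95)
  )
}

# Rasterize one star-convex cell into a tight crop. Returns mask, granule
# label matrix (truth granules, clipped to the mask) and crop size.
rasterize_cell <- function(truth_row, config) {
  m <- 24L
  pert <- config$shape_perturbation
  vr <- truth_row$radius * (1 + pert * runif(m, -1, 1))
  L <- 2L * ceiling(max(vr)) + 9L
  c0 <- (L + 1) / 2
  xs <- seq_len(L) - c0
  px <- expand.grid(x = xs, y = xs)
  theta <- atan2(px$y, px$x) %% (2 * pi)
  # linear interpolation of vertex radii around the circle
  step <- 2 * pi / m
  j <- floor(theta / step)
  frac <- theta / step - j
  rj <- vr[(j %% m) + 1L]
  rj1 <- vr[((j + 1L) %% m) + 1L]
  rmax_theta <- rj * (1 - frac) + rj1 * frac
  inside <- sqrt(px$x^2 + px$y^2) <= rmax_theta
  mask <- matrix(as.integer(inside), L, L)
  gran <- matrix(0L, L, L)
  k <- truth_row$n_granules
  if (k > 0) {
    ang <- runif(k, 0, 2 * pi)
    rad_frac <- sqrt(runif(k)) * 0.7
    gr <- runif(k, config$granule_radius[1], config$granule_radius[2])
    # local boundary radius at each granule angle
    jg <- floor((ang %% (2 * pi)) / step)
    fg <- (ang %% (2 * pi)) / step - jg
    rbound <- vr[(jg %% m) + 1L] * (1 - fg) + vr[((jg + 1L) %% m) + 1L] * fg
    gx <- rad_frac * rbound * cos(ang)
    gy <- rad_frac * rbound * sin(ang)
    for (i in seq_len(k)) {
      hit <- (px$x - gx[i])^2 + (px$y - gy[i])^2 <= gr[i]^2 & inside
      gran[hit] <- i
    }
  }
  list(mask = mask, granules = gran, crop = L)
}

# Normalized decay shape (sums to 1) over n_bins mid-point bins of one period.
decay_shape <- function(tau, rep_rate, n_bins) {
  period <- 1e3 / rep_rate # ns
  t <- (seq_len(n_bins) - 0.5) * period / n_bins
  sh <- exp(-t / tau)
  list(t = t, shape = sh / sum(sh))
}

# Photon-weighted moments of cos/sin under a decay shape; used both for the
# analytic phasor value and for the shot-noise (delta-method) covariance.
shape_moments <- function(shape, t, rep_rate) {
  omega <- 2 * pi * rep_rate * 1e6 * 1e-9
  cv <- cos(omega * t); sv <- sin(omega * t)
  c(g = sum(shape * cv), s = sum(shape * sv),
    c2 = sum(shape * cv^2), s2 = sum(shape * sv^2), cs = sum(shape * cv * sv))
}

# Render one condition of one rasterized cell. Returns intensity, g, s
# matrices over the crop. method "decay": synthesize per-pixel 256-bin decay
# histograms with shot noise and Fourier-transform them. method "analytic":
# closed-form mixture phasor + delta-method Gaussian shot noise (the fast
# path; mutual oracle of the decay path).
render_condition <- function(rast, truth_row, f_bound, config,
                             method = c("decay", "analytic")) {
  method <- match.arg(method)
  L <- rast$crop
  inside <- rast$mask > 0
  is_gran <- rast$granules > 0 & inside
  npx <- sum(inside)
  lam <- truth_row$base_intensity * rlnorm(npx, 0, config$texture_sdlog)
  lam[is_gran[inside]] <- lam[is_gran[inside]] * config$granule_amp
  sf <- decay_shape(config$tau_free, config$rep_rate, config$n_bins)
  sb <- decay_shape(config$tau_bound, config$rep_rate, config$n_bins)
  sl <- decay_shape(config$lipo_tau, config$rep_rate, config$n_bins)
  mix_nadh <- f_bound * sb$shape + (1 - f_bound) * sf$shape
  mix_gran <- config$lipo_weight * sl$shape +
    (1 - config$lipo_weight) * mix_nadh
  intensity <- matrix(0, L, L)
  g_map <- matrix(NA_real_, L, L)
  s_map <- matrix(NA_real_, L, L)
  gran_flag <- is_gran[inside]
  if (method == "decay") {
    counts <- matrix(0, npx, config$n_bins)
    exp_counts <- matrix(0, npx, config$n_bins)
    if (any(!gran_flag)) exp_counts[!gran_flag, ] <- lam[!gran_flag] %o% mix_nadh
    if (any(gran_flag)) exp_counts[gran_flag, ] <- lam[gran_flag] %o% mix_gran
    counts[] <- if (config$poisson)
      rpois(length(exp_counts), exp_counts) else exp_counts
    tot <- rowSums(counts)
    omega <- 2 * pi * config$rep_rate * 1e6 * 1e-9
    cv <- cos(omega * sf$t); sv <- sin(omega * sf$t)
    g <- as.numeric(counts %*% cv) / tot
    s <- as.numeric(counts %*% sv) / tot
    g[tot <= 0] <- NA_real_
    s[tot <= 0] <- NA_real_
    ivals <- tot
  } else {
    ivals <- if (config$poisson) rpois(npx, lam) else lam
    g <- s <- numeric(npx)
    for (grp in c(FALSE, TRUE)) {
      sel <- gran_flag == grp
      if (!any(sel)) next
      mom <- shape_moments(if (grp) mix_gran else mix_nadh, sf$t,
                           config$rep_rate)
      if (config$poisson) {
        n_ph <- pmax(ivals[sel], 1)
        vg <- (mom["c2"] - mom["g"]^2) / n_ph
        vs <- (mom["s2"] - mom["s"]^2) / n_ph
        cgs <- (mom["cs"] - mom["g"] * mom["s"]) / n_ph
        z1 <- rnorm(sum(sel)); z2 <- rnorm(sum(sel))
        a <- sqrt(pmax(vg, 0))
        b <- ifelse(a > 0, cgs / a, 0)
        cc <- sqrt(pmax(vs - b^2, 0))
        g[sel] <- mom["g"] + a * z1
        s[sel] <- mom["s"] + b * z1 + cc * z2
      } else {
        g[sel] <- mom["g"]
        s[sel] <- mom["s"]
      }
    }
    g[ivals <= 0] <- NA_real_
    s[ivals <= 0] <- NA_real_
  }
  if (config$gaussian_sd > 0)
    ivals <- pmax(ivals + rnorm(npx, 0, config$gaussian_sd), 0)
  intensity[inside] <- ivals
  g_map[inside] <- g
  s_map[inside] <- s
  list(intensity = intensity, g_map = g_map, s_map = s_map)
}

embed_crop <- function(crop_mat, image_size, fill = 0) {
  L <- nrow(crop_mat)
  if (L > image_size)
    stop("synthetic cell crop (", L, " px) exceeds image_size ", image_size)
  out <- matrix(fill, image_size, image_size)
  off <- floor((image_size - L) / 2)
  out[off + seq_len(L), off + seq_len(L)] <- crop_mat
  out
}

make_bundles <- function(truth_row, config, method, full_size = TRUE) {
  rast <- rasterize_cell(truth_row, config)
  conds <- list(low = list(mM = 2.2, f = truth_row$f_bound_low),
                high = list(mM = 16.7, f = truth_row$f_bound_high))
  out <- lapply(conds, function(cd) {
    r <- render_condition(rast, truth_row, cd$f, config, method)
    if (full_size) {
      cell_bundle(truth_row$cell_id, truth_row$islet_id, truth_row$donor_id,
                  cd$mM,
                  embed_crop(r$intensity, config$image_size),
                  embed_crop(r$g_map, config$image_size, NA_real_),
                  embed_crop(r$s_map, config$image_size, NA_real_),
                  embed_crop(rast$mask, config$image_size))
    } else {
      cell_bundle(truth_row$cell_id, truth_row$islet_id, truth_row$donor_id,
                  cd$mM, r$intensity, r$g_map, r$s_map, rast$mask)
    }
  })
  names(out) <- c("low", "high")
  out
}

#' Generate a synthetic islet cohort of image bundles
#'
#' Renders `n_cells` star-convex cells, each with a 2.2 mM and a 16.7 mM
#' glucose bundle (intensity, g, s rasters plus ROI mask), with
#' class-conditional effects injected per the configuration: beta cells get
#' twice the lipofuscin granule load, brighter autofluorescence and a larger
#' glucose-induced shift of the NAD(P)H phasor toward the bound pole.
#' Per-pixel decays are synthesised as two-component exponential mixtures
#' (plus a lipofuscin component inside granules) and transformed to phasor
#' coordinates; a fixed seed gives bit-identical cohorts.
#'
#' @param config a [synth_config()].
#' @param method `"decay"` (default, full decay-histogram synthesis) or
#'   `"analytic"` (closed-form phasor + shot-noise approximation).
#' @return list of class `synthetic_cohort`: `bundles` (per cell: `$low`,
#'   `$high` [cell_bundle()]s), `labels` (tibble `cell_id`, `cell_type`),
#'   `donor_table`, `truth` (per-cell generative parameters), `config`.
#' @export
generate_cohort <- function(config, method = c("decay", "analytic")) {
  method <- match.arg(method)
  stopifnot(inherits(config, "synth_config"))
  bytes <- config$n_cells * 2 * 4 * as.numeric(config$image_size)^2 * 8
  if (bytes > 4e9)
    stop("generate_cohort(): cohort would need ~", round(bytes / 1e9),
         " GB of rasters; lower n_cells/image_size or use ",
         "generate_feature_matrix()")
  set.seed(config$seed)
  donors <- sample_donor_table(config)
  truth <- sample_truth(config, donors)
  bundles <- lapply(seq_len(config$n_cells), function(i)
    make_bundles(truth[i, ], config, method))
  names(bundles) <- truth$cell_id
  structure(list(
    bundles = bundles,
    labels = tibble(cell_id = truth$cell_id,
                    cell_type = factor(truth$type, levels = c("alpha", "beta"))),
    donor_table = donors, truth = truth, config = config
  ), class = "synthetic_cohort")
}

#' Generate a synthetic feature matrix directly
#'
#' The fast path of the generator: renders each cell's bundles in memory
#' (cropped to the cell's bounding box, never written to disk) and extracts
#' its 151-feature record immediately. With `method = "analytic"` the
#' per-pixel phasor coordinates are drawn from the closed-form mixture value
#' plus the delta-method shot-noise distribution instead of synthesising and
#' Fourier-transforming full decay histograms; the two methods agree in
#' distribution and serve as mutual oracles in the test suite.
#'
#' @inheritParams generate_cohort
#' @return tibble as from [build_feature_matrix()] (identifiers, `cell_type`
#'   label, 151 features), with the per-cell `truth` table attached as
#'   attribute `"truth"`.
#' @export
generate_feature_matrix <- function(config, method = c("analytic", "decay")) {
  method <- match.arg(method)
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  donors <- sample_donor_table(config)
  truth <- sample_truth(config, donors)
  records <- lapply(seq_len(config$n_cells), function(i) {
    tr <- truth[i, ]
    b <- make_bundles(tr, config, method, full_size = FALSE)
    extract_cell_features(b$low, b$high,
                          donors[donors$donor_id == tr$donor_id, ],
                          label = tr$type,
                          rep_rate = config$rep_rate,
                          tau_free = config$tau_free,
                          tau_bound = config$tau_bound)
  })
  out <- build_feature_matrix(records, layout = config$layout)
  attr(out, "truth") <- truth
  out
}

#' Emit a truth-based cleaning manifest for a synthetic cohort
#'
#' Emulates manual dataset cleaning by flagging a random subset of cells
#' with audit reason codes, so the manifest-driven cleaning path and the
#' excluded-data stability check can be exercised without real images.
#'
#' @param cell_ids character vector of cohort cell ids.
#' @param fraction fraction of cells to exclude.
#' @param seed integer seed.
#' @return tibble `cell_id`, `reason` (one of the audit reason codes).
#' @export
synthetic_manifest <- function(cell_ids, fraction = 0.1, seed = 1L) {
  set.seed(seed)
  cell_ids <- unique(cell_ids)
  n <- max(0L, round(length(cell_ids) * fraction))
  picked <- sample(cell_ids, n)
  reasons <- c("ambiguous-identity", "rearrangement", "focal-plane-mismatch",
               "shape-change", "duplicate")
  tibble(cell_id = picked,
         reason = sample(reasons, n, replace = TRUE))
}

#' Write a synthetic cohort to disk
#'
#' Per-cell TIFF stacks (intensity, g, s; 32-bit float) and mask TIFFs, a
#' CSV donor table and a JSON truth-parameter sidecar. Requires the
#' \pkg{tiff} package.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("write_cohort() needs the 'tiff' package")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  norm01 <- function(m) {
    m[!is.finite(m)] <- 0
    m
  }
  for (cid in names(cohort$bundles)) {
    for (cond in c("low", "high")) {
      b <- cohort$bundles[[cid]][[cond]]
      base <- file.path(dir, paste0(cid, "_", cond))
      tiff::writeTIFF(norm01(b$intensity / max(b$intensity, 1)),
                      paste0(base, "_intensity.tif"), bits.per.sample = 32L)
      tiff::writeTIFF(norm01(b$g_map), paste0(base, "_g.tif"),
                      bits.per.sample = 32L)
      tiff::writeTIFF(norm01(b$s_map), paste0(base, "_s.tif"),
                      bits.per.sample = 32L)
      tiff::writeTIFF(b$roi_mask + 0, paste0(base, "_mask.tif"),
                      bits.per.sample = 32L)
    }
  }
  utils::write.csv(cohort$donor_table, file.path(dir, "donors.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}
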