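#' Descriptive-statistics block of a pixel value population
#'
#' The twelve general-purpose summary statistics applied to every signal and
#' pixel subset in the feature schema: `min`, `max`, `mean`, `median`, `sd`,
#' `q1`, `q3`, `iqr`, `whisker_low`, `whisker_high`, `mode`, `skew`.
#'
#' Conventions (frozen so the schema is reproducible):
#' * quantiles use linear interpolation (R type 7);
#' * whiskers are Tukey's: the most extreme observations still within
#'   `[q1 - 1.5 iqr, q3 + 1.5 iqr]`;
#' * `mode` is the center of the fullest bin of a 64-bin histogram over
#'   `[min, max]` (first bin wins ties; equals the value itself when the
#'   population is constant);
#' * `skew` is the population moment coefficient \eqn{m_3 / m_2^{3/2}}
#'   (0 when the population is constant);
#' * `sd` uses the sample (n-1) denominator.
#'
#' @param values numeric vector; `NA`s are dropped. An empty population
#'   returns an all-`NA` block (downstream imputation maps it to 0, meaning
#'   absence of signal).
#' @return named numeric vector of length 12.
#' @export
descriptive_stats <- function(values) {
  nm <- c("min", "max", "mean", "median", "sd", "q1", "q3", "iqr",
          "whisker_low", "whisker_high", "mode", "skew")
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0L) return(setNames(rep(NA_real_, 12L), nm))
  qs <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- qs[3] - qs[1]
  in_fence <- values[values >= qs[1] - 1.5 * iqr & values <= qs[3] + 1.5 * iqr]
  rng <- range(values)
  if (rng[1] == rng[2]) {
    mode_c <- rng[1]
    skew <- 0
  } else {
    breaks <- seq(rng[1], rng[2], length.out = 65L)
    counts <- tabulate(
      findInterval(values, breaks, rightmost.closed = TRUE, all.inside = TRUE),
      nbins = 64L)
    b <- which.max(counts)
    mode_c <- (breaks[b] + breaks[b + 1L]) / 2
    m <- mean(values)
    m2 <- mean((values - m)^2)
    skew <- if (m2 > 0) mean((values - m)^3) / m2^1.5 else 0
  }
  setNames(c(rng[1], rng[2], mean(values), qs[2],
             if (n > 1L) sd(values) else 0,
             qs[1], qs[3], iqr, min(in_fence), max(in_fence), mode_c, skew),
           nm)
}

stat_names <- c("min", "max", "mean", "median", "sd", "q1", "q3", "iqr",
                "whisker_low", "whisker_high", "mode", "skew")

#' The frozen 151-feature schema
#'
#' Enumerates, in canonical column order, the 151 per-cell features the
#' pipeline extracts: descriptive-statistics blocks over
#' (signal x pixel subset x glucose condition), per-condition phasor,
#' lipofuscin and metabolism singletons, cell morphology, donor covariates
#' and the experimental glucose indicator. The schema is generated by code
#' (not stored) so column order is reproducible; [write_schema_json()]
#' serialises it alongside any exported feature matrix.
#'
#' Families and counts:
#' * `intensity` (74): 12 statistics of autofluorescence intensity over all /
#'   lipofuscin / non-lipofuscin pixels, per condition, plus total photon
#'   count per condition;
#' * `phasor` (54): 12 statistics of the lipofuscin-excluded per-pixel g and
#'   s coordinates per condition, plus cloud dispersion and phase/modulation
#'   lifetimes of the barycenter per condition;
#' * `lipofuscin` (10): granule area fraction, count, mean size, density
#'   (granules per 1000 cell px) and granule/NAD(P)H intensity ratio, per
#'   condition;
#' * `metabolism` (6): bound-fraction estimate per condition and the four
#'   glucose-shift descriptors (delta g, delta s, magnitude, projection on
#'   the free-to-bound axis);
#' * `morphology` (3): area, perimeter, circularity;
#' * `donor` (3): age, BMI, stimulatory index;
#' * `experimental` (1): the row's glucose condition (0 = 2.2 mM,
#'   1 = 16.7 mM).
#'
#' @return tibble with columns `name`, `family`, `signal`, `subset`,
#'   `condition`, `statistic`; exactly 151 rows, unique names.
#' @export
feature_schema <- function() {
  if (!is.null(.schema_cache$schema)) return(.schema_cache$schema)
  .schema_cache$schema <- build_feature_schema()
  .schema_cache$schema
}

.schema_cache <- new.env(parent = emptyenv())

build_feature_schema <- function() {
  conds <- c("lowG", "highG")
  blocks <- list()
  add <- function(name, family, signal, subset, condition, statistic) {
    blocks[[length(blocks) + 1L]] <<-
      tibble(name = name, family = family, signal = signal, subset = subset,
             condition = condition, statistic = statistic)
  }
  for (cond in conds) {
    for (sub in c("all", "lipo", "nonlipo"))
      add(paste("intensity", sub, stat_names, cond, sep = "_"),
          "intensity", "intensity", sub, cond, stat_names)
    for (sig in c("g", "s"))
      add(paste(sig, stat_names, cond, sep = "_"),
          "phasor", sig, "nonlipo", cond, stat_names)
    add(paste0("intensity_total_", cond), "intensity", "intensity", "all",
        cond, "total")
    add(paste(c("phasor_dispersion", "tau_phase", "tau_mod"), cond, sep = "_"),
        "phasor", "phasor", "nonlipo", cond,
        c("dispersion", "tau_phase", "tau_mod"))
    add(paste(c("lipo_area_fraction", "lipo_granule_count",
                "lipo_mean_granule_size", "lipo_granule_density",
                "lipo_intensity_ratio"), cond, sep = "_"),
        "lipofuscin", "lipofuscin", "lipo", cond,
        c("area_fraction", "count", "mean_size", "density", "intensity_ratio"))
    add(paste0("bound_fraction_", cond), "metabolism", "phasor", "nonlipo",
        cond, "bound_fraction")
  }
  add(paste0("shift_", c("delta_g", "delta_s", "magnitude", "projection")),
      "metabolism", "phasor", "nonlipo", "both",
      c("delta_g", "delta_s", "magnitude", "projection"))
  add(paste0("morph_", c("area", "perimeter", "circularity")),
      "morphology", "mask", "all", "both", c("area", "perimeter", "circularity"))
  add(paste0("donor_", c("age", "bmi", "si")),
      "donor", "clinical", "all", "both", c("age", "bmi", "si"))
  add("exp_glucose", "experimental", "protocol", "all", "row",
      "glucose_indicator")
  schema <- dplyr::bind_rows(blocks)
  stopifnot(nrow(schema) == 151L, !anyDuplicated(schema$name))
  schema
}

#' Serialise / read a feature schema sidecar
#'
#' @param schema tibble from [feature_schema()].
#' @param path JSON file path.
#' @return `write_schema_json()` returns `path` invisibly;
#'   `read_schema_json()` returns the schema tibble.
#' @export
write_schema_json <- function(schema, path) {
  jsonlite::write_json(schema, path, dataframe = "rows", auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_schema_json
#' @export
read_schema_json <- function(path) {
  as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}
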