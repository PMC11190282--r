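#' Construct a per-cell image bundle
#'
#' The raw unit of analysis: one segmented cell at one glucose condition,
#' with its autofluorescence intensity image, per-pixel phasor coordinate
#' maps and ROI mask, all sharing the same shape.
#'
#' @param cell_id,islet_id,donor_id identifiers.
#' @param condition glucose concentration in mM (2.2 or 16.7).
#' @param intensity,g_map,s_map numeric matrices.
#' @param roi_mask binary matrix, non-empty.
#' @return list of class `cell_bundle`.
#' @export
cell_bundle <- function(cell_id, islet_id, donor_id, condition,
                        intensity, g_map, s_map, roi_mask) {
  stopifnot(condition %in% c(2.2, 16.7))
  dims <- list(dim(intensity), dim(g_map), dim(s_map), dim(roi_mask))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("cell_bundle(): rasters of cell ", cell_id, " differ in shape")
  if (!any(roi_mask > 0)) stop("cell_bundle(): empty ROI mask for cell ", cell_id)
  structure(list(cell_id = cell_id, islet_id = islet_id, donor_id = donor_id,
                 condition = condition, intensity = intensity, g_map = g_map,
                 s_map = s_map, roi_mask = roi_mask),
            class = "cell_bundle")
}

# All per-condition features of one bundle plus the phasor summary needed
# for the cross-condition shift. Returns list(features = named numeric,
# summary = cloud_summary tibble).
condition_features <- function(bundle, cond_tag, free_point, bound_point,
                               rep_rate = 80, lipo_n_mad = 3,
                               lipo_min_size = 4L) {
  inside <- bundle$roi_mask > 0
  granules <- lipofuscin_mask(bundle$intensity, bundle$roi_mask,
                              n_mad = lipo_n_mad, min_size = lipo_min_size)
  lipo <- granules$granule_mask > 0
  ivals <- bundle$intensity
  feats <- c()
  subsets <- list(all = inside, lipo = inside & lipo, nonlipo = inside & !lipo)
  for (sub in names(subsets)) {
    block <- descriptive_stats(ivals[subsets[[sub]]])
    names(block) <- paste("intensity", sub, names(block), cond_tag, sep = "_")
    feats <- c(feats, block)
  }
  nonlipo <- subsets$nonlipo
  for (sig in c("g", "s")) {
    block <- descriptive_stats(bundle[[paste0(sig, "_map")]][nonlipo])
    names(block) <- paste(sig, names(block), cond_tag, sep = "_")
    feats <- c(feats, block)
  }
  feats[paste0("intensity_total_", cond_tag)] <- sum(ivals[inside])
  cloud <- tibble(g = bundle$g_map[nonlipo], s = bundle$s_map[nonlipo])
  cloud <- cloud[is.finite(cloud$g) & is.finite(cloud$s), ]
  if (nrow(cloud) > 0L) {
    cs <- cloud_summary(cloud)
    taus <- phasor_lifetimes(cs$barycenter_g, cs$barycenter_s, rep_rate)
    feats[paste0("phasor_dispersion_", cond_tag)] <- sqrt(cs$sd_g^2 + cs$sd_s^2)
    feats[paste0("tau_phase_", cond_tag)] <- taus[["tau_phase"]]
    feats[paste0("tau_mod_", cond_tag)] <- taus[["tau_mod"]]
    feats[paste0("bound_fraction_", cond_tag)] <-
      bound_fraction_estimate(cs$barycenter_g, cs$barycenter_s,
                              free_point, bound_point)
  } else {
    cs <- NULL
    feats[paste0(c("phasor_dispersion_", "tau_phase_", "tau_mod_",
                   "bound_fraction_"), cond_tag)] <- NA_real_
  }
  ratio <- if (granules$n_granules > 0L)
    mean(ivals[subsets$lipo]) / mean(ivals[nonlipo]) else NA_real_
  feats[paste0("lipo_area_fraction_", cond_tag)] <- granules$area_fraction
  feats[paste0("lipo_granule_count_", cond_tag)] <- granules$n_granules
  feats[paste0("lipo_mean_granule_size_", cond_tag)] <-
    if (granules$n_granules > 0L) mean(granules$granule_areas) else NA_real_
  feats[paste0("lipo_granule_density_", cond_tag)] <-
    1000 * granules$n_granules / granules$cell_area
  feats[paste0("lipo_intensity_ratio_", cond_tag)] <- ratio
  list(features = feats, summary = cs)
}

#' Extract the 151-feature record of one cell
#'
#' Turns the low- and high-glucose image bundles of one cell, plus its donor
#' covariates, into a named feature vector conforming to [feature_schema()].
#' Lipofuscin granules are segmented per condition with [lipofuscin_mask()];
#' phasor statistics and the metabolic shift use the lipofuscin-excluded
#' pixel population (pixel-exclusion reading of lipofuscin-signal
#' subtraction). Pixel populations that are empty (e.g. a cell without
#' granules) yield `NA` features, later imputed to 0 to mean absence of
#' signal.
#'
#' @param low,high `cell_bundle`s of the same cell at 2.2 and 16.7 mM.
#' @param donor one-row data frame with `age`, `bmi`, `si`.
#' @param label cell identity: `"alpha"`, `"beta"` or `"unknown"`.
#' @param pixel_size physical pixel size (default 1: pixel units).
#' @param rep_rate laser repetition rate, MHz.
#' @param tau_free,tau_bound reference free / bound NAD(P)H lifetimes (ns)
#'   defining the metabolic axis.
#' @param lipo_n_mad,lipo_min_size lipofuscin threshold policy, see
#'   [lipofuscin_mask()].
#' @return list of class `cell_record`: identifiers, `label`, and `features`
#'   (named numeric, length 151, `exp_glucose` left `NA` until the matrix
#'   layout assigns it).
#' @export
extract_cell_features <- function(low, high, donor, label = "unknown",
                                  pixel_size = 1, rep_rate = 80,
                                  tau_free = 0.4, tau_bound = 3.4,
                                  lipo_n_mad = 3, lipo_min_size = 4L) {
  stopifnot(inherits(low, "cell_bundle"), inherits(high, "cell_bundle"))
  if (!identical(low$cell_id, high$cell_id))
    stop("extract_cell_features(): bundle pair mixes cells ",
         low$cell_id, " and ", high$cell_id)
  if (low$condition >= high$condition)
    stop("extract_cell_features(): expected conditions 2.2 then 16.7 mM")
  free_point <- unlist(phasor_of_lifetime(tau_free, rep_rate)[, c("g", "s")])
  bound_point <- unlist(phasor_of_lifetime(tau_bound, rep_rate)[, c("g", "s")])
  fl <- condition_features(low, "lowG", free_point, bound_point, rep_rate,
                           lipo_n_mad, lipo_min_size)
  fh <- condition_features(high, "highG", free_point, bound_point, rep_rate,
                           lipo_n_mad, lipo_min_size)
  feats <- c(fl$features, fh$features)
  if (!is.null(fl$summary) && !is.null(fh$summary)) {
    sh <- metabolic_shift(fl$summary, fh$summary, free_point, bound_point)
    feats[c("shift_delta_g", "shift_delta_s",
            "shift_magnitude", "shift_projection")] <-
      c(sh$delta_g, sh$delta_s, sh$magnitude, sh$projection)
  } else {
    feats[c("shift_delta_g", "shift_delta_s",
            "shift_magnitude", "shift_projection")] <- NA_real_
  }
  morph <- mask_morphology(low$roi_mask, pixel_size, cell_id = low$cell_id)
  feats[c("morph_area", "morph_perimeter", "morph_circularity")] <-
    c(morph$area, morph$perimeter, morph$circularity)
  feats[c("donor_age", "donor_bmi", "donor_si")] <-
    c(donor$age, donor$bmi, donor$si)
  feats["exp_glucose"] <- NA_real_
  schema <- feature_schema()
  feats <- feats[schema$name]
  stopifnot(length(feats) == 151L, !any(is.na(names(feats))))
  structure(list(cell_id = low$cell_id, islet_id = low$islet_id,
                 donor_id = low$donor_id, label = label, features = feats),
            class = "cell_record")
}

#' Assemble cell records into a feature matrix and target vector
#'
#' Stacks `cell_record`s into a tidy table: identifier columns, the class
#' label `cell_type`, then the 151 schema features. Row order is canonical
#' (sorted by donor, islet, cell, condition) so shuffled inputs yield an
#' identical matrix.
#'
#' @param records list of `cell_record`s sharing one schema.
#' @param layout `"per_condition"` (default): each cell contributes one row
#'   per glucose condition; the two rows share the pair-derived features and
#'   differ in `exp_glucose` (0 = 2.2 mM, 1 = 16.7 mM). `"per_cell"`: one
#'   row per cell, `exp_glucose` is `NA` (imputed to 0 downstream).
#' @return tibble with columns `cell_id`, `islet_id`, `donor_id`,
#'   `condition`, `cell_type`, then the 151 feature columns. Zero records
#'   give an empty tibble with the full header.
#' @export
build_feature_matrix <- function(records,
                                 layout = c("per_condition", "per_cell")) {
  layout <- match.arg(layout)
  schema <- feature_schema()
  empty <- as_tibble(c(
    list(cell_id = character(), islet_id = character(),
         donor_id = character(), condition = character(),
         cell_type = factor(character(), levels = c("alpha", "beta"))),
    setNames(rep(list(numeric()), 151L), schema$name)))
  if (length(records) == 0L) return(empty)
  nm0 <- names(records[[1]]$features)
  rows <- purrr::map(records, function(rec) {
    stopifnot(inherits(rec, "cell_record"))
    if (!identical(names(rec$features), nm0))
      stop("build_feature_matrix(): records use mixed feature schemas")
    base <- tibble(cell_id = as.character(rec$cell_id),
                   islet_id = as.character(rec$islet_id),
                   donor_id = as.character(rec$donor_id),
                   cell_type = factor(rec$label, levels = c("alpha", "beta")))
    if (layout == "per_condition") {
      out <- dplyr::bind_rows(base, base)
      out$condition <- c("2.2", "16.7")
      fm <- rbind(rec$features, rec$features)
      fm[, "exp_glucose"] <- c(0, 1)
    } else {
      out <- base
      out$condition <- "both"
      fm <- rbind(rec$features)
    }
    dplyr::bind_cols(out, as_tibble(fm))
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$donor_id, .data$islet_id, .data$cell_id,
                        .data$condition)
  dplyr::select(out, "cell_id", "islet_id", "donor_id", "condition",
                "cell_type", dplyr::all_of(schema$name))
}

#' Identify the feature columns of an assembled matrix
#'
#' @param data tibble from [build_feature_matrix()] or
#'   [generate_feature_matrix()].
#' @return character vector of the 151 schema column names present in `data`.
#' @export
feature_columns <- function(data) {
  intersect(feature_schema()$name, names(data))
}

#' Write a feature matrix as CSV with a JSON schema sidecar
#'
#' @param data assembled feature tibble.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.schema.json`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  write_schema_json(feature_schema(), paste0(path, ".schema.json"))
  invisible(path)
}
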