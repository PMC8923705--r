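#' Pipeline configuration
#'
#' All tunable parameters of the normalization and functional pipelines in
#' one serialisable object. `config_hash` gives a stable hash embedded in
#' reports for provenance.
#'
#' @param binning A [polar_binning].
#' @param degree_L Incident-profile polynomial degree.
#' @param profile_floor Floor on the normalised incident profile.
#' @param otsu_bins Histogram bins for Otsu thresholds.
#' @param delta_d_mm Depth bin width (mm); `NULL` = one voxel.
#' @param fit_depth_range_mm Depth window for the Beer-Lambert fit.
#' @param depth_cap_mm Attenuation gain cap depth.
#' @param attenuation_fit_on Volume feeding the decay fit:
#'   `"compensated"` (incident-compensated, consistent with the division it
#'   later normalises) or `"raw"`.
#' @param scales A [vessel_scales].
#' @param frangi_alpha,frangi_beta,frangi_c_frac Frangi parameters.
#' @param so2_threshold_pct Artery/vein classification threshold.
#' @param thb_floor sO2 mask floor (`NULL` = robust default).
#' @param clahe_tiles,clahe_clip CLAHE baseline parameters.
#' @return An object of class `oat_config`.
#' @export
oat_config <- function(binning = polar_binning(), degree_L = 2L,
                       profile_floor = 0.05, otsu_bins = 256L,
                       delta_d_mm = NULL, fit_depth_range_mm = c(0, 30),
                       depth_cap_mm = 35,
                       attenuation_fit_on = c("compensated", "raw"),
                       scales = vessel_scales(), frangi_alpha = 0.5,
                       frangi_beta = 0.5, frangi_c_frac = 0.5,
                       so2_threshold_pct = artery_vein_threshold(),
                       thb_floor = NULL,
                       clahe_tiles = c(8, 8, 4), clahe_clip = 0.01) {
  attenuation_fit_on <- match.arg(attenuation_fit_on)
  structure(as.list(environment()), class = "oat_config")
}

#' @rdname oat_config
#' @param config An `oat_config`.
#' @export
config_hash <- function(config) {
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                        digits = NA, force = TRUE)
  # small stable polynomial hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Normalize the optical fluence of multiwavelength volumes
#'
#' The full measurement-data-driven normalization, in order: (1) estimate
#' and divide out the angular incident-fluence profile per wavelength;
#' (2) estimate the breast surface and per-voxel depth once, from the first
#' wavelength's compensated volume (the breast is held static in the cup,
#' so one surface serves all wavelengths); (3) fit and divide out the
#' Beer-Lambert depth decay per wavelength (the effective attenuation is
#' wavelength-dependent).
#'
#' @param vols Named list of [gridded_volume]s (names = wavelengths), or a
#'   single volume.
#' @param config An [oat_config].
#' @return An object of class `oat_normalization`: `normalized` (list of
#'   volumes), `surface` (`surface_estimate`), `profiles`
#'   (`incident_profile` per wavelength), `attenuation`
#'   (`attenuation_model` per wavelength), `config`, `config_hash`.
#' @export
run_normalize <- function(vols, config = oat_config()) {
  if (is_gridded_volume(vols)) vols <- list(vols)
  if (length(vols) < 1) stop("need at least one volume", call. = FALSE)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))

  profiles <- list(); comped <- list()
  for (i in seq_along(vols)) {
    mvbp <- stage("incident", angular_mvbp(vols[[i]], config$binning))
    profiles[[i]] <- stage("incident",
                           fit_incident_profile(mvbp, config$degree_L))
    comped[[i]] <- compensate_incident(vols[[i]], profiles[[i]],
                                       floor = config$profile_floor)
  }
  surface <- stage("surface", estimate_surface(comped[[1]],
                                               n_bins = config$otsu_bins))
  atten <- list(); normalized <- list()
  for (i in seq_along(vols)) {
    fit_vol <- if (config$attenuation_fit_on == "compensated")
      comped[[i]] else vols[[i]]
    binned <- stage("attenuation",
                    depth_binned_max(fit_vol, surface$depth,
                                     mask = surface$mask,
                                     delta_d = config$delta_d_mm))
    atten[[i]] <- stage("attenuation",
                        fit_beer_lambert(binned, config$fit_depth_range_mm))
    normalized[[i]] <- compensate_attenuation(comped[[i]], atten[[i]],
                                              surface, config$depth_cap_mm)
  }
  names(normalized) <- names(profiles) <- names(atten) <- names(vols)
  structure(list(normalized = normalized, surface = surface,
                 profiles = profiles, attenuation = atten, config = config,
                 config_hash = config_hash(config)),
            class = "oat_normalization")
}

#' Unmix, detect and classify; score against ground truth when available
#'
#' Functional half of the pipeline: spectral unmixing of the (normalized)
#' per-wavelength volumes into hemoglobin maps and sO2; multiscale Frangi
#' enhancement and Otsu detection on the total-hemoglobin map; artery/vein
#' classification of detected voxels by sO2 threshold; and, when a phantom
#' truth is supplied, the full task-metric report.
#'
#' @param vols Named list of [gridded_volume]s, one per wavelength
#'   (normalized or not, depending on the arm under study).
#' @param table An [extinction_table] matching the wavelengths.
#' @param config An [oat_config].
#' @param mask Optional 0/1 [gridded_volume] restricting detection (e.g.
#'   the estimated breast mask).
#' @param truth Optional `phantom_truth` for evaluation.
#' @param truth_depth Optional depth map for depth-binned metrics (defaults
#'   to the truth's own depth map).
#' @return An object of class `oat_functional`: `maps`
#'   (`chromophore_maps`), `so2`, `vesselness`, `detected`, `labels`, and —
#'   with truth — `metrics` (det/tar/tvr/acc/dtar/dtvr/dacc and the
#'   per-depth-bin table).
#' @export
run_functional <- function(vols, table, config = oat_config(), mask = NULL,
                           truth = NULL, truth_depth = NULL) {
  if (length(vols) < 2) stop("need >= 2 wavelengths for unmixing",
                             call. = FALSE)
  maps <- unmix(vols, table)
  so2 <- so2_map(maps, thb_floor = config$thb_floor)
  vness <- frangi_vesselness(maps$c_thb, config$scales,
                             alpha = config$frangi_alpha,
                             beta = config$frangi_beta,
                             c_frac = config$frangi_c_frac)
  detected <- detect_vessels(vness, mask = mask)
  labels <- classify_artery_vein(so2, detected,
                                 threshold_pct = config$so2_threshold_pct)
  out <- list(maps = maps, so2 = so2, vesselness = vness,
              detected = detected, labels = labels,
              config_hash = config_hash(config))
  if (!is.null(truth)) {
    truth_lab <- truth_vessel_labels(truth)
    # known-structure classification: score sO2 at every true vessel voxel
    known <- classify_known_structure(so2, truth_lab,
                                      config$so2_threshold_pct)
    det <- detection_metrics(detected, truth_lab)
    accs <- classification_metrics(known, truth_lab, "known_structure")
    daccs <- classification_metrics(labels, truth_lab, "detected_structure",
                                    detected = detected)
    dd <- if (is.null(truth_depth)) truth$depth_true else truth_depth
    per_bin <- depth_binned_metrics(known, truth_lab, detected, dd)
    out$metrics <- c(list(det = det), accs, daccs, list(per_depth_bin = per_bin))
  }
  structure(out, class = "oat_functional")
}

# truth labels as 0/1/2 volume (none/artery/vein)
truth_vessel_labels <- function(truth) {
  lab <- truth$tissue_labels$data
  out <- array(0, dim = dim(lab))
  out[lab == PHANTOM_LABELS[["artery"]]] <- 1
  out[lab == PHANTOM_LABELS[["vein"]]] <- 2
  with_data(truth$tissue_labels, out)
}

# classify every truth vessel voxel from the sO2 map (structure assumed known)
classify_known_structure <- function(so2, truth_lab, threshold_pct) {
  lab <- array(0, dim = dim(so2$data))
  vess <- truth_lab$data %in% c(1, 2) & !is.na(so2$data)
  lab[vess & so2$data >= threshold_pct] <- 1
  lab[vess & so2$data < threshold_pct] <- 2
  with_data(so2, lab)
}
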