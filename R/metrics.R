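#' Peak signal-to-noise ratio
#'
#' `10 * log10(MAX^2 / MSE)` in dB over all voxels; identical volumes give
#' `Inf`.
#'
#' @param x,ref [gridded_volume]s on the same grid.
#' @param max_alpha Maximum possible voxel brightness (e.g. 255 for 8-bit).
#' @return Scalar in dB.
#' @export
psnr <- function(x, ref, max_alpha = 255) {
  assert_same_grid(x, ref)
  mse <- mean((x$data - ref$data)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_alpha^2 / mse)
}

#' Structural similarity index (volumetric, Gaussian window)
#'
#' Mean over voxels of the local SSIM map computed with Gaussian local
#' statistics (sigma = 1.5 voxels, 11^3 support) and stabilisation constants
#' `C1 = (K1 * MAX)^2`, `C2 = (K2 * MAX)^2` with the conventional
#' `K1 = 0.01`, `K2 = 0.03`.
#'
#' @inheritParams psnr
#' @param k1,k2 Stabilisation constants (defaults 0.01, 0.03).
#' @param sigma Gaussian window sigma in voxels (default 1.5).
#' @return Scalar in `[-1, 1]`.
#' @export
ssim <- function(x, ref, max_alpha = 255, k1 = 0.01, k2 = 0.03,
                 sigma = 1.5) {
  assert_same_grid(x, ref)
  d <- dim(x$data)
  sm <- function(a) array(cpp_gauss3(as.vector(a), d, sigma), dim = d)
  mx <- sm(x$data); my <- sm(ref$data)
  sxx <- sm(x$data^2) - mx^2
  syy <- sm(ref$data^2) - my^2
  sxy <- sm(x$data * ref$data) - mx * my
  c1 <- (k1 * max_alpha)^2; c2 <- (k2 * max_alpha)^2
  map <- ((2 * mx * my + c1) * (2 * sxy + c2)) /
    ((mx^2 + my^2 + c1) * (sxx + syy + c2))
  mean(map)
}

#' Physical image-quality metrics against a differently scaled reference
#'
#' PSNR and SSIM between an image estimate and a reference whose units
#' differ (e.g. reconstructed brightness vs true absorption coefficient).
#' Both volumes are independently min-max rescaled to `[0, 255]` before
#' comparison, with `MAX = 255`; the rescale convention is part of the
#' report.
#'
#' @param x,ref [gridded_volume]s on the same grid.
#' @return Named list `psnr_db`, `ssim`, and the convention used.
#' @export
image_quality <- function(x, ref) {
  rs <- function(v) {
    rng <- range(v$data)
    s <- if (diff(rng) == 0) v$data * 0 else (v$data - rng[1]) / diff(rng) * 255
    with_data(v, s)
  }
  xs <- rs(x); rr <- rs(ref)
  list(psnr_db = psnr(xs, rr, 255), ssim = ssim(xs, rr, 255),
       normalization = "per-volume min-max rescale to [0,255]")
}

# voxel counts shared by the task metrics
vessel_counts <- function(truth_labels) {
  lab <- truth_labels$data
  c(n_a = sum(lab == 1), n_v = sum(lab == 2))
}

#' Blood-vessel detectability index
#'
#' `DET = N_hat_AV / (N_A + N_V) * 100`: the percentage of true
#' artery/vein voxels that fall inside the detected vessel set.
#'
#' @param detected 0/1 [gridded_volume] from [detect_vessels()].
#' @param truth_labels [gridded_volume] with 0 = none, 1 = artery, 2 = vein.
#' @return Scalar percentage.
#' @export
detection_metrics <- function(detected, truth_labels) {
  assert_same_grid(detected, truth_labels)
  nn <- vessel_counts(truth_labels)
  if (sum(nn) == 0) stop("truth contains no vessel voxels", call. = FALSE)
  n_av <- sum(detected$data > 0 & truth_labels$data %in% c(1, 2))
  100 * n_av / sum(nn)
}

#' Artery/vein classification accuracy
#'
#' In `known_structure` mode the vascular structure is assumed known and
#' every true vessel voxel is scored on its predicted class (true artery
#' rate TAR, true vein rate TVR, and their vessel-count-weighted mean ACC).
#' In `detected_structure` mode only voxels that are both detected and
#' correctly classified count (DTAR, DTVR, DACC), so the rates fold in
#' detection failures. An empty truth class leaves its rate `NA`.
#'
#' @param pred_labels [gridded_volume] of predicted labels (1 = artery,
#'   2 = vein, 0 = none).
#' @param truth_labels [gridded_volume] of true labels.
#' @param mode `"known_structure"` or `"detected_structure"`.
#' @param detected 0/1 [gridded_volume]; required for
#'   `"detected_structure"`.
#' @return Named list: `tar`, `tvr`, `acc` (or `dtar`, `dtvr`, `dacc`).
#' @export
classification_metrics <- function(pred_labels, truth_labels,
                                   mode = c("known_structure",
                                            "detected_structure"),
                                   detected = NULL) {
  mode <- match.arg(mode)
  assert_same_grid(pred_labels, truth_labels)
  nn <- vessel_counts(truth_labels)
  correct <- pred_labels$data == truth_labels$data &
    truth_labels$data %in% c(1, 2)
  if (mode == "detected_structure") {
    if (is.null(detected)) stop("`detected` required", call. = FALSE)
    correct <- correct & detected$data > 0
  }
  n_ta <- sum(correct & truth_labels$data == 1)
  n_tv <- sum(correct & truth_labels$data == 2)
  tar <- if (nn["n_a"] > 0) 100 * n_ta / nn["n_a"] else NA_real_
  tvr <- if (nn["n_v"] > 0) 100 * n_tv / nn["n_v"] else NA_real_
  acc <- if (sum(nn) > 0) 100 * (n_ta + n_tv) / sum(nn) else NA_real_
  out <- list(unname(tar), unname(tvr), unname(acc))
  names(out) <- if (mode == "known_structure") c("tar", "tvr", "acc") else
    c("dtar", "dtvr", "dacc")
  out
}

#' Depth-binned detectability and classification accuracy
#'
#' DET and ACC restricted to true vessel voxels within each half-open depth
#' bin `[10k, 10(k+1))` mm (default five 10-mm bins). Bins without vessel
#' voxels are `NA`.
#'
#' @param pred_labels,truth_labels,detected As in the global metrics.
#' @param depth [gridded_volume] depth map defined on truth-vessel voxels
#'   (ground-truth depth when available, else the estimated one).
#' @param bin_edges_mm Increasing edges (default `seq(0, 50, 10)`).
#' @return `data.frame` with per-bin `depth_lo_mm`, `depth_hi_mm`,
#'   `n_vessel`, `det`, `acc`.
#' @export
depth_binned_metrics <- function(pred_labels, truth_labels, detected, depth,
                                 bin_edges_mm = seq(0, 50, 10)) {
  assert_same_grid(truth_labels, depth)
  nb <- length(bin_edges_mm) - 1L
  vess <- truth_labels$data %in% c(1, 2)
  out <- data.frame(depth_lo_mm = bin_edges_mm[-(nb + 1L)],
                    depth_hi_mm = bin_edges_mm[-1L],
                    n_vessel = NA_integer_, det = NA_real_, acc = NA_real_)
  for (i in seq_len(nb)) {
    sel <- vess & !is.na(depth$data) &
      depth$data >= bin_edges_mm[i] & depth$data < bin_edges_mm[i + 1L]
    n <- sum(sel)
    out$n_vessel[i] <- n
    if (n == 0) next
    out$det[i] <- 100 * sum(detected$data[sel] > 0) / n
    out$acc[i] <- 100 * sum(pred_labels$data[sel] == truth_labels$data[sel]) / n
  }
  out
}

#' Reference task-metric table
#'
#' Published benchmark detectability/classification table for two- and
#' three-wavelength unmixing of a simulated breast under three processing
#' arms (no normalization, 3D CLAHE, fluence normalization), bundled for
#' arithmetic cross-checks of the summary improvement ratios.
#'
#' @return `data.frame` with columns `wavelengths`, `normalization`, `det`,
#'   `tar`, `tvr`, `acc`, `dtar`, `dtvr`, `dacc`.
#' @export
reference_task_metrics <- function() {
  read.csv(system.file("extdata", "reference_task_metrics.csv",
                       package = "oatnorm", mustWork = TRUE),
           stringsAsFactors = FALSE)
}

#' Average improvement ratios of a task-metric table
#'
#' For each wavelength combination, the ratio of the fluence-normalized
#' arm's DET (and DACC) to the unnormalized and CLAHE arms, averaged over
#' combinations.
#'
#' @param metrics Table in the layout of [reference_task_metrics()].
#' @return Named list `det_vs_none`, `det_vs_clahe`, `dacc_vs_none`,
#'   `dacc_vs_clahe`.
#' @export
average_improvement_ratios <- function(metrics = reference_task_metrics()) {
  sp <- split(metrics, metrics$wavelengths)
  one <- function(df, col) {
    p <- df[[col]][df$normalization == "proposed"]
    c(none = p / df[[col]][df$normalization == "none"],
      clahe = p / df[[col]][df$normalization == "clahe"])
  }
  det <- vapply(sp, one, numeric(2), col = "det")
  dacc <- vapply(sp, one, numeric(2), col = "dacc")
  list(det_vs_none = mean(det["none", ]),
       det_vs_clahe = mean(det["clahe", ]),
       dacc_vs_none = mean(dacc["none", ]),
       dacc_vs_clahe = mean(dacc["clahe", ]))
}
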