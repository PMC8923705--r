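#' Vessel-enhancement scale set
#'
#' Widths (in voxels) of the tubular structures to enhance. A width of w
#' voxels maps to a Gaussian scale sigma = w/2 voxels (a tube of diameter w
#' responds maximally near sigma of about half its diameter). The default
#' widths 1-5 voxels correspond to 0.25-1.25 mm vessels at 0.25 mm voxels,
#' representative of breast vasculature.
#'
#' @param scale_widths_voxels Increasing positive widths (default `1:5`).
#' @param voxel_size_mm Voxel size, used only for reporting widths in mm.
#' @return An object of class `vessel_scales`.
#' @export
vessel_scales <- function(scale_widths_voxels = 1:5, voxel_size_mm = NULL) {
  w <- as.numeric(scale_widths_voxels)
  stopifnot(length(w) >= 1, all(w > 0), !is.unsorted(w, strictly = TRUE))
  structure(list(scale_widths_voxels = w, voxel_size_mm = voxel_size_mm,
                 sigmas_voxels = w / 2),
            class = "vessel_scales")
}

#' Multiscale Frangi vesselness
#'
#' 3D vessel-enhancement filter: at each scale the volume is smoothed with a
#' Gaussian, the Hessian is formed from scale-normalised second differences,
#' and the eigenvalues (|l1| <= |l2| <= |l3|) feed the tube/plate/blob
#' discriminants; bright tubes on a dark background require l2, l3 < 0. The
#' per-voxel response is the maximum over scales and lies in [0, 1]. The
#' structureness cutoff c is set per scale to `c_frac` times the maximum
#' Frobenius norm of the Hessian, so the response is invariant to a global
#' rescaling of the input.
#'
#' @param vol A [gridded_volume].
#' @param scales A [vessel_scales].
#' @param alpha,beta Plate/blob discriminant sensitivities (defaults 0.5).
#' @param c_frac Structureness cutoff as a fraction of the per-scale maximum
#'   Hessian Frobenius norm (default 0.5).
#' @return A [gridded_volume] of vesselness in [0, 1].
#' @export
frangi_vesselness <- function(vol, scales = vessel_scales(), alpha = 0.5,
                              beta = 0.5, c_frac = 0.5) {
  d <- dim(vol$data)
  best <- numeric(prod(d))
  for (sg in scales$sigmas_voxels) {
    r <- cpp_frangi_scale(as.vector(vol$data), d, sg, alpha, beta, c_frac)
    best <- pmax(best, r)
  }
  with_data(vol, array(best, dim = d))
}

#' Detect vessels by Otsu thresholding of vesselness
#'
#' Foreground = vesselness above the Otsu threshold of the in-mask
#' vesselness values; out-of-mask voxels are never detected. A degenerate
#' (constant) vesselness histogram yields an empty detection with a warning.
#'
#' @param vesselness A [gridded_volume] from [frangi_vesselness()].
#' @param mask Optional 0/1 [gridded_volume] restricting the detection
#'   domain (e.g. the breast mask).
#' @return A 0/1 [gridded_volume].
#' @export
detect_vessels <- function(vesselness, mask = NULL) {
  m <- if (is.null(mask)) array(TRUE, dim(vesselness$data)) else mask$data > 0
  vals <- vesselness$data[m]
  t_otsu <- tryCatch(otsu_threshold(vals), error = function(e) {
    warning("degenerate vesselness histogram; empty detection")
    Inf
  })
  det <- array(0, dim = dim(vesselness$data))
  det[m & vesselness$data >= t_otsu] <- 1
  with_data(vesselness, det)
}

#' Artery/vein classification threshold
#'
#' The arithmetic mean of the nominal arterial and venous oxygenation
#' levels; with the default 97% (artery) and 70% (vein) this is 83.5%.
#'
#' @param artery_so2_pct,vein_so2_pct Nominal oxygenation levels (percent).
#' @return Scalar threshold in percent.
#' @export
artery_vein_threshold <- function(artery_so2_pct = 97, vein_so2_pct = 70) {
  (artery_so2_pct + vein_so2_pct) / 2
}

#' Classify detected vessel voxels into arteries and veins
#'
#' Detected voxels with `sO2 >= threshold` are labelled arteries and the
#' remainder veins (a voxel exactly at the threshold is an artery). Detected
#' voxels whose sO2 is undefined are labelled none.
#'
#' @param so2 A [gridded_volume] of sO2 (percent, possibly `NA`-masked).
#' @param detected A 0/1 [gridded_volume] from [detect_vessels()].
#' @param threshold_pct Classification threshold (default 83.5).
#' @return A [gridded_volume] with labels 0 = none, 1 = artery, 2 = vein.
#' @export
classify_artery_vein <- function(so2, detected,
                                 threshold_pct = artery_vein_threshold()) {
  assert_same_grid(so2, detected)
  lab <- array(0, dim = dim(so2$data))
  det <- detected$data > 0 & !is.na(so2$data)
  lab[det & so2$data >= threshold_pct] <- 1
  lab[det & so2$data < threshold_pct] <- 2
  with_data(so2, lab)
}
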