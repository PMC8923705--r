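#' Polar-angle binning specification
#'
#' Bins of width `delta_theta_deg` whose centres run from `theta_min_deg` to
#' `theta_max_deg`; bin i covers the half-open interval
#' `(theta_i - delta/2, theta_i + delta/2]`. The default range 90-160 degrees
#' spans chest wall to the edge of the areola region; angles above 160
#' degrees (nipple/areola, whose pigment violates the vessels-are-brightest
#' assumption) are excluded from profile fitting.
#'
#' @param delta_theta_deg Bin width in degrees (default 1).
#' @param theta_min_deg,theta_max_deg Fit range in degrees (defaults 90, 160).
#' @return An object of class `polar_binning`.
#' @export
polar_binning <- function(delta_theta_deg = 1, theta_min_deg = 90,
                          theta_max_deg = 160) {
  stopifnot(delta_theta_deg > 0, theta_min_deg >= 0,
            theta_min_deg < theta_max_deg, theta_max_deg <= 180)
  structure(list(delta_theta_deg = delta_theta_deg,
                 theta_min_deg = theta_min_deg,
                 theta_max_deg = theta_max_deg),
            class = "polar_binning")
}

bin_centers <- function(binning) {
  seq(binning$theta_min_deg, binning$theta_max_deg,
      by = binning$delta_theta_deg)
}

# half-open (lo, hi] assignment of angles to bins; NA outside range
assign_theta_bins <- function(theta, binning) {
  lo <- binning$theta_min_deg - binning$delta_theta_deg / 2
  hi <- binning$theta_max_deg + binning$delta_theta_deg / 2
  idx <- ceiling((theta - lo) / binning$delta_theta_deg)
  idx[!is.finite(theta) | theta <= lo | theta > hi] <- NA_integer_
  idx
}

#' Maximum voxel brightness per polar-angle bin (MVBP)
#'
#' The brightest voxel in each polar-angle bin. Under the assumptions that
#' subdermal vessels are present at every polar angle and are the strongest
#' absorbers, these per-bin maxima trace the angular profile of the incident
#' optical fluence.
#'
#' @param vol A [gridded_volume] of reconstructed brightness.
#' @param binning A [polar_binning].
#' @return `data.frame` with `theta_deg` (bin centres) and `max_brightness`
#'   (`NA` for empty bins).
#' @export
angular_mvbp <- function(vol, binning = polar_binning()) {
  theta <- polar_angle_map(vol)
  idx <- assign_theta_bins(theta, binning)
  keep <- !is.na(idx)
  if (!any(keep)) stop("no-voxels-in-range", call. = FALSE)
  centers <- bin_centers(binning)
  mx <- rep(NA_real_, length(centers))
  got <- tapply(vol$data[keep], idx[keep], max)
  mx[as.integer(names(got))] <- as.numeric(got)
  data.frame(theta_deg = centers, max_brightness = mx)
}

#' Fit the angular incident-fluence profile
#'
#' Ordinary least-squares fit of a degree-L polynomial `q_L(theta)` to the
#' per-bin maximum brightness, then normalised so the profile peaks at 1 over
#' the fit range. Degree 1 suits single-source illumination; degree 2 suits
#' the simulated multi-segment illumination.
#'
#' @param bins MVBP table from [angular_mvbp()].
#' @param degree_L Polynomial degree (`>= 0`).
#' @return An object of class `incident_profile` with fields `coeffs`
#'   (unnormalised, highest degree first), `degree_L`, `fit_range_deg`,
#'   `normalization` (peak of the raw polynomial over the fit range).
#' @export
fit_incident_profile <- function(bins, degree_L = 2L) {
  stopifnot(degree_L >= 0)
  ok <- !is.na(bins$max_brightness)
  if (sum(ok) <= degree_L)
    stop("not enough non-missing bins for the requested degree", call. = FALSE)
  th <- bins$theta_deg[ok]; y <- bins$max_brightness[ok]
  if (length(unique(th)) <= degree_L)
    stop("degenerate design: too few distinct angles", call. = FALSE)
  if (degree_L == 0) {
    cf <- mean(y)
  } else {
    fit <- lm(y ~ poly(th, degree_L, raw = TRUE))
    cf <- rev(coef(fit))                       # highest degree first
    cf[is.na(cf)] <- 0
  }
  rng <- range(bins$theta_deg)
  grid <- seq(rng[1], rng[2], length.out = 4001L)
  norm <- max(polyval_hf(cf, grid))
  if (!is.finite(norm) || norm <= 0)
    stop("fitted profile is non-positive over the fit range", call. = FALSE)
  structure(list(coeffs = unname(cf), degree_L = degree_L,
                 fit_range_deg = rng, normalization = norm),
            class = "incident_profile")
}

# evaluate polynomial with highest-degree-first coefficients
polyval_hf <- function(cf, x) {
  out <- rep(0, length(x))
  for (c_i in cf) out <- out * x + c_i
  out
}

#' Evaluate a normalised incident profile
#'
#' Evaluates `q_L(theta) / normalization` with theta clamped to the fit range
#' (the polynomial is never extrapolated) and the result floored at `floor`
#' so the subsequent division cannot blow up where the polynomial approaches
#' zero or goes negative.
#'
#' @param profile An [incident_profile][fit_incident_profile].
#' @param theta_deg Numeric vector/array of polar angles; `NA` evaluates to 1
#'   (unit gain).
#' @param floor Lower bound on the normalised profile (default 0.05).
#' @return Values in `[floor, 1]` with the shape of `theta_deg`.
#' @export
eval_incident_profile <- function(profile, theta_deg, floor = 0.05) {
  th <- pmin(profile$fit_range_deg[2], pmax(profile$fit_range_deg[1], theta_deg))
  q <- polyval_hf(profile$coeffs, th) / profile$normalization
  q <- pmax(q, floor)
  q[is.na(theta_deg)] <- 1
  q
}

#' Compensate nonuniform incident fluence
#'
#' Elementwise division of the reconstructed volume by the normalised
#' incident-fluence profile evaluated at each voxel's polar angle. Because
#' the profile peaks at 1, compensation is a relative gain `>= 1` applied
#' where the illumination was weaker (typically toward the chest wall).
#' Voxels outside the fit range (above the chest-wall plane, or in the
#' nipple/areola cone) are compensated with theta clamped to the range edge.
#'
#' @inheritParams eval_incident_profile
#' @param vol A [gridded_volume] (the reconstructed brightness).
#' @return A [gridded_volume] on the same grid.
#' @export
compensate_incident <- function(vol, profile, floor = 0.05) {
  theta <- polar_angle_map(vol)
  g <- eval_incident_profile(profile, theta, floor = floor)
  with_data(vol, vol$data / g)
}
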