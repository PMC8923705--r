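#' Depth-binned maximum vessel brightness
#'
#' Maximum in-mask voxel brightness within each depth bin. Bin m (0-based)
#' covers depths `[m*delta_d, (m+1)*delta_d)` with centre `(m + 1/2)*delta_d`;
#' the default bin width is one voxel. Under the assumption that vessels are
#' present and are the strongest absorbers throughout the depth range, these
#' maxima trace the Beer-Lambert decay of the fluence.
#'
#' @param vol A [gridded_volume] (by default the incident-compensated
#'   brightness).
#' @param depth A [gridded_volume] depth map (mm, `NA` outside the mask).
#' @param mask Optional 0/1 [gridded_volume]; defaults to `!is.na(depth)`.
#' @param delta_d Bin width in mm (default: one voxel).
#' @return `data.frame` with `depth_mm` (bin centres) and `max_brightness`
#'   (`NA` for empty bins).
#' @export
depth_binned_max <- function(vol, depth, mask = NULL, delta_d = NULL) {
  assert_same_grid(vol, depth)
  if (is.null(delta_d)) delta_d <- vol$voxel_size_mm
  inmask <- if (is.null(mask)) !is.na(depth$data) else
    (mask$data > 0 & !is.na(depth$data))
  if (!any(inmask)) stop("no in-mask voxels", call. = FALSE)
  d <- depth$data[inmask]
  idx <- floor(d / delta_d) + 1L
  nb <- max(idx)
  mx <- rep(NA_real_, nb)
  got <- tapply(vol$data[inmask], idx, max)
  mx[as.integer(names(got))] <- as.numeric(got)
  data.frame(depth_mm = (seq_len(nb) - 0.5) * delta_d, max_brightness = mx)
}

#' Fit the Beer-Lambert decay to depth-binned maxima
#'
#' Nonlinear least squares of `c * exp(-mu * d)` to the positive depth-binned
#' maxima, initialised by log-linear regression, with `mu` constrained
#' nonnegative. If the optimiser fails, the log-linear estimate is returned
#' with a warning. Bins deeper than `fit_depth_range_mm[2]` are excluded from
#' the fit: at large depth the per-bin maximum is dominated by the noise
#' floor rather than vessel signal, which would flatten the fitted decay.
#'
#' @param binned Table from [depth_binned_max()].
#' @param fit_depth_range_mm Length-2 depth window (mm) used for fitting
#'   (default `c(0, 30)`).
#' @return An object of class `attenuation_model` with fields `c_star`,
#'   `mu_eff_star` (mm^-1), `fit_depth_range_mm`, `binned_max`.
#' @export
fit_beer_lambert <- function(binned, fit_depth_range_mm = c(0, 30)) {
  sel <- !is.na(binned$max_brightness) & binned$max_brightness > 0 &
    binned$depth_mm >= fit_depth_range_mm[1] &
    binned$depth_mm <= fit_depth_range_mm[2]
  if (sum(sel) < 3) stop("need >= 3 positive bins in the fit range",
                         call. = FALSE)
  d <- binned$depth_mm[sel]; y <- binned$max_brightness[sel]
  ll <- lm(log(y) ~ d)
  mu0 <- max(0, -coef(ll)[[2]]); c0 <- exp(coef(ll)[[1]])
  if (max(abs(c0 * exp(-mu0 * d) - y)) <= 1e-12 * max(y)) {
    # the log-linear initialisation already fits exactly (noise-free or
    # constant bins); the NLS step would be degenerate
    return(structure(list(c_star = c0, mu_eff_star = mu0,
                          fit_depth_range_mm = fit_depth_range_mm,
                          binned_max = binned),
                     class = "attenuation_model"))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ cc * exp(-mu * d),
                      start = list(cc = c0, mu = mu0),
                      lower = c(cc = 1e-12, mu = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warning("nonlinear fit failed; falling back to log-linear estimate")
    cc <- c0; mu <- mu0
  } else {
    cc <- coef(fit)[["cc"]]; mu <- coef(fit)[["mu"]]
  }
  structure(list(c_star = cc, mu_eff_star = mu,
                 fit_depth_range_mm = fit_depth_range_mm,
                 binned_max = binned),
            class = "attenuation_model")
}

#' @export
print.attenuation_model <- function(x, ...) {
  cat(sprintf(
    "<attenuation_model> c* = %.4g, mu_eff* = %.4g mm^-1 (%.3f cm^-1)\n",
    x$c_star, x$mu_eff_star, mu_eff_cm(x)))
  invisible(x)
}

#' Effective attenuation coefficient in cm^-1
#'
#' Attenuation coefficients are stored in mm^-1 (world units are mm) and
#' reported in cm^-1, the unit used in the optical literature.
#'
#' @param model An [attenuation_model][fit_beer_lambert].
#' @return Scalar, `mu_eff_star * 10`.
#' @export
mu_eff_cm <- function(model) model$mu_eff_star * 10

#' Compensate depth-dependent optical attenuation
#'
#' Divides each in-mask voxel by `exp(-mu_eff* d)` (the fitted decay
#' normalised to 1 at the surface, so shallow voxels are not rescaled) and
#' zeroes all out-of-mask voxels. The divisor is floored at
#' `exp(-mu_eff* depth_cap_mm)`, capping the gain so that noise at large
#' depth is not amplified without bound.
#'
#' @param vol A [gridded_volume] (the incident-compensated brightness).
#' @param model An [attenuation_model][fit_beer_lambert].
#' @param surface A `surface_estimate` providing `mask` and `depth`.
#' @param depth_cap_mm Gain cap depth in mm (default 35).
#' @return A [gridded_volume]: compensated in-mask, exactly 0 outside.
#' @export
compensate_attenuation <- function(vol, model, surface, depth_cap_mm = 35) {
  assert_same_grid(vol, surface$mask)
  mu <- model$mu_eff_star
  inmask <- surface$mask$data > 0 & !is.na(surface$depth$data)
  out <- array(0, dim = dim(vol$data))
  d <- surface$depth$data[inmask]
  divisor <- pmax(exp(-mu * d), exp(-mu * depth_cap_mm))
  out[inmask] <- vol$data[inmask] / divisor
  with_data(vol, out)
}
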