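#' Per-voxel polar angle
#'
#' Polar angle theta (degrees, measured from the positive z axis) of every
#' voxel centre, `theta = acos(z / r)` with `r = sqrt(x^2 + y^2 + z^2)`.
#' With the package's coordinate convention the chest wall lies at 90 degrees
#' and the nipple pole at 180 degrees. A voxel exactly at the world origin has
#' no defined polar angle and carries `NA`; it is excluded from any angular
#' binning.
#'
#' @param vol A [gridded_volume]; only its grid geometry is used.
#' @return A 3D array of angles in `[0, 180]` degrees (`NA` at the origin).
#' @export
polar_angle_map <- function(vol) {
  x <- coord_array(vol, "x"); y <- coord_array(vol, "y")
  z <- coord_array(vol, "z")
  r <- sqrt(x^2 + y^2 + z^2)
  th <- acos(pmin(pmax(z / r, -1), 1)) * 180 / pi
  th[r == 0] <- NA_real_
  th
}

#' Per-voxel cylindrical radius
#'
#' Distance of every voxel centre from the z axis, `rho = sqrt(x^2 + y^2)` mm.
#'
#' @param vol A [gridded_volume]; only its grid geometry is used.
#' @return A 3D array of radii (mm).
#' @export
radial_distance_map <- function(vol) {
  x <- coord_array(vol, "x"); y <- coord_array(vol, "y")
  sqrt(x^2 + y^2)
}

#' Rotationally symmetric spheroid surface model
#'
#' The breast surface is modelled as the surface of revolution (about the z
#' axis) of the ellipse `(z - zc)^2 / a^2 + rho^2 / b^2 = 1`.
#'
#' @param a_mm Semi-axis along z (mm), positive.
#' @param b_mm Semi-axis along the cylindrical radius (mm), positive.
#' @param zc_mm z coordinate of the ellipse centre (mm).
#' @return An object of class `surface_model`.
#' @export
surface_model <- function(a_mm, b_mm, zc_mm = 0) {
  if (!is.finite(a_mm) || a_mm <= 0 || !is.finite(b_mm) || b_mm <= 0)
    stop("semi-axes must be positive", call. = FALSE)
  structure(list(a_mm = a_mm, b_mm = b_mm, zc_mm = zc_mm),
            class = "surface_model")
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf("<surface_model> a = %.3f mm, b = %.3f mm, zc = %.3f mm\n",
              x$a_mm, x$b_mm, x$zc_mm))
  invisible(x)
}

# signed interior test: < 1 inside
spheroid_residual <- function(points, surf) {
  rho2 <- points[, 1]^2 + points[, 2]^2
  (points[, 3] - surf$zc_mm)^2 / surf$a_mm^2 + rho2 / surf$b_mm^2
}

#' Minimum distance from interior points to a spheroid surface
#'
#' Depth of a point below the modelled breast surface: the minimum Euclidean
#' distance to the spheroid. Rotational symmetry reduces the problem to
#' point-to-ellipse distance in the (rho, z) half-plane, which by the
#' ellipse's mirror symmetries folds into the first quadrant with ordered
#' semi-axes. There the stationarity condition of the squared distance has a
#' unique root of the strictly decreasing function
#' `F(t) = (e0 y0/(t+e0^2))^2 + (e1 y1/(t+e1^2))^2 - 1`
#' inside a closed-form bracket; a bracket-safeguarded Newton iteration on
#' `F` (bisection step whenever Newton would leave the bracket) converges
#' for every query. On-axis queries have closed forms (including the
#' inside-the-evolute case where the nearest point is off-axis).
#'
#' @param points Numeric matrix (n x 3) of world coordinates (mm), or a
#'   length-3 vector for a single point. All points must be strictly inside
#'   the spheroid.
#' @param surf A [surface_model].
#' @param tol Convergence tolerance on the root residual.
#' @param max_iter Maximum Newton/bisection iterations.
#' @return Numeric vector of depths (mm), `>= 0`.
#' @export
spheroid_depth <- function(points, surf, tol = 1e-6, max_iter = 100L) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (any(spheroid_residual(points, surf) >= 1))
    stop("outside-surface: all points must lie strictly inside the spheroid",
         call. = FALSE)
  # fold to first quadrant with e0 >= e1 (a, b are scalars)
  w0 <- sqrt(points[, 1]^2 + points[, 2]^2)        # rho >= 0
  w1 <- abs(points[, 3] - surf$zc_mm)              # |z - zc|
  if (surf$a_mm > surf$b_mm) {
    y0 <- w1; y1 <- w0; e0 <- surf$a_mm; e1 <- surf$b_mm
  } else {
    y0 <- w0; y1 <- w1; e0 <- surf$b_mm; e1 <- surf$a_mm
  }
  e0s <- e0^2; e1s <- e1^2
  ftol <- min(tol, 1e-12)

  d <- numeric(length(y0))
  gen <- y0 > 0 & y1 > 0
  if (any(gen)) {
    g0 <- e0 * y0[gen]; g1 <- e1 * y1[gen]
    t_lo <- -e1s + g1
    t_hi <- -e1s + sqrt(g0^2 + g1^2)
    t <- (t_lo + t_hi) / 2
    for (it in seq_len(max_iter)) {
      f <- (g0 / (t + e0s))^2 + (g1 / (t + e1s))^2 - 1
      if (all(abs(f) < ftol)) break
      t_lo[f > 0] <- t[f > 0]; t_hi[f < 0] <- t[f < 0]
      fp <- -2 * (g0^2 / (t + e0s)^3 + g1^2 / (t + e1s)^3)
      tn <- t - f / fp
      out <- !is.finite(tn) | tn <= t_lo | tn >= t_hi
      tn[out] <- (t_lo[out] + t_hi[out]) / 2     # safeguard: bisect
      t <- tn
    }
    x0 <- e0s * y0[gen] / (t + e0s)
    x1 <- e1s * y1[gen] / (t + e1s)
    d[gen] <- sqrt((x0 - y0[gen])^2 + (x1 - y1[gen])^2)
  }
  ax <- !gen & y1 == 0 & y0 > 0                    # on the long axis
  if (any(ax)) {
    cusp <- (e0s - e1s) / e0
    inside_evolute <- y0[ax] < cusp
    x0 <- ifelse(inside_evolute, e0s * y0[ax] / max(e0s - e1s, 1e-300), e0)
    x1 <- ifelse(inside_evolute, e1 * sqrt(pmax(0, 1 - (x0 / e0)^2)), 0)
    d[ax] <- sqrt((x0 - y0[ax])^2 + x1^2)
  }
  sh <- !gen & !ax & y0 == 0 & y1 > 0              # on the short axis
  d[sh] <- e1 - y1[sh]
  d[y0 == 0 & y1 == 0] <- e1                       # centre
  d
}
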