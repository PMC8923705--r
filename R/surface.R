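#' Emphasise vessels for surface detection
#'
#' A 3x3x3 median filter (edge-replicated) to suppress isolated noise voxels,
#' followed by an elementwise square to boost the contrast of the remaining
#' bright vessel voxels. Applied to the incident-compensated volume before
#' Otsu extraction of subdermal vessel voxels.
#'
#' @param vol A [gridded_volume] (incident-compensated brightness).
#' @return A [gridded_volume] on the same grid.
#' @export
vessel_emphasis <- function(vol) {
  m <- cpp_median3(as.vector(vol$data), dim(vol$data))
  with_data(vol, array(m^2, dim = dim(vol$data)))
}

#' Otsu threshold of a volume
#'
#' Global threshold maximising the between-class variance of an `n_bins`
#' histogram spanning the value range. Returns the lower edge of the first
#' bin of the upper class, so the foreground is `{value >= T}`.
#'
#' @param x A [gridded_volume] or numeric vector/array.
#' @param n_bins Number of histogram bins (default 256).
#' @return Scalar threshold.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- if (is_gridded_volume(x)) as.vector(x$data) else as.vector(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0)
    stop("degenerate-histogram: volume is constant", call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  b <- pmin(n_bins, pmax(1L, findInterval(v, breaks, rightmost.closed = TRUE)))
  counts <- tabulate(b, nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w <- cumsum(counts)                      # class-0 size for cut after bin k
  m <- cumsum(counts * mids)               # class-0 mass
  n <- w[n_bins]; mu <- m[n_bins]
  k <- seq_len(n_bins - 1L)
  w0 <- w[k]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  sb <- rep(-Inf, n_bins - 1L)
  sb[valid] <- (mu * w0[valid] / n - m[k][valid])^2 /
    (w0[valid] / n * w1[valid] / n)
  # ties (e.g. empty-bin plateaus between well-separated classes) resolve to
  # the middle of the maximal plateau
  best <- which(sb == max(sb))
  kbest <- best[ceiling(length(best) / 2)]
  breaks[kbest + 1L]
}

#' Per-slice breast radius from extracted vessel voxels
#'
#' For each z slice, the maximum cylindrical radius among extracted
#' (above-threshold) voxels: the outermost subdermal vessels trace the breast
#' boundary.
#'
#' @param mask_v Logical 3D array (or [gridded_volume] of 0/1): the extracted
#'   voxel set V.
#' @param grid A [gridded_volume] supplying the grid geometry (required when
#'   `mask_v` is a plain array).
#' @return `data.frame` with `z_mm` and `rho_mm` (`NA` for slices without
#'   extracted voxels).
#' @export
slice_radii <- function(mask_v, grid = NULL) {
  if (is_gridded_volume(mask_v)) {
    grid <- mask_v; m <- mask_v$data > 0
  } else m <- mask_v > 0
  if (is.null(grid)) stop("`grid` required for plain-array input", call. = FALSE)
  if (!any(m)) stop("extracted voxel set V is empty", call. = FALSE)
  rho <- radial_distance_map(grid)
  zc <- axis_coords(grid)$z
  nz <- length(zc)
  out <- rep(NA_real_, nz)
  slice <- rep(seq_len(nz), each = prod(dim(m)[1:2]))
  got <- tapply(rho[m], slice[as.vector(m)], max)
  out[as.integer(names(got))] <- as.numeric(got)
  data.frame(z_mm = zc, rho_mm = out)
}

#' Fit the rotationally symmetric spheroid to slice radii
#'
#' Least-squares fit of the ellipse `(z - zc)^2/a^2 + rho^2/b^2 = 1` to the
#' per-slice radii, minimising the algebraic residual
#' `((z - zc)^2/a^2 + rho^2/b^2 - 1)^2`. Algebraic (rather than geometric
#' point-to-curve) residuals keep the fit a plain nonlinear least-squares
#' problem with no inner root-find. Initialised from the data extents.
#'
#' @param radii Table from [slice_radii()].
#' @return A [surface_model].
#' @export
fit_ellipse <- function(radii) {
  ok <- !is.na(radii$rho_mm)
  z <- radii$z_mm[ok]; rho <- radii$rho_mm[ok]
  if (length(z) < 3 || length(unique(z)) < 3)
    stop("need >= 3 slices with radii at >= 3 distinct z", call. = FALSE)
  start <- c(a = max(diff(range(z)), 1e-2), b = max(rho), zc = max(z))
  resid <- function(p) (z - p[3])^2 / p[1]^2 + rho^2 / p[2]^2 - 1
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid,
                       lower = c(1e-3, 1e-3, -Inf),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("ellipse fit failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  cf <- coef(fit)
  if (!all(is.finite(cf)) || cf[["a"]] <= 0 || cf[["b"]] <= 0)
    stop("ellipse fit returned non-positive axes", call. = FALSE)
  surface_model(cf[["a"]], cf[["b"]], cf[["zc"]])
}

#' Breast mask and depth map from a fitted surface
#'
#' The breast mask is 1 for voxels strictly inside the spheroid and 0
#' outside (boundary voxels count as outside); the depth map holds, for every
#' in-mask voxel, the minimum distance to the spheroid surface (mm), and `NA`
#' outside the mask.
#'
#' @param model A [surface_model].
#' @param grid A [gridded_volume] supplying the grid.
#' @param tol,max_iter Passed to [spheroid_depth()].
#' @return An object of class `surface_estimate` with fields `model`, `mask`
#'   (0/1 [gridded_volume]) and `depth` ([gridded_volume], `NA` outside).
#' @export
build_mask_and_depth <- function(model, grid, tol = 1e-6, max_iter = 50L) {
  x <- coord_array(grid, "x"); y <- coord_array(grid, "y")
  z <- coord_array(grid, "z")
  res <- (z - model$zc_mm)^2 / model$a_mm^2 + (x^2 + y^2) / model$b_mm^2
  inside <- res < 1
  depth <- array(NA_real_, dim = dim(grid$data))
  if (any(inside)) {
    pts <- cbind(x[inside], y[inside], z[inside])
    depth[inside] <- spheroid_depth(pts, model, tol = tol,
                                    max_iter = max_iter)
  }
  structure(list(model = model,
                 mask = with_data(grid, array(as.numeric(inside),
                                              dim = dim(grid$data))),
                 depth = with_data(grid, depth, allow_na = TRUE),
                 slice_radii = NULL, otsu_threshold = NULL),
            class = "surface_estimate")
}

#' Estimate the breast surface from an incident-compensated volume
#'
#' Full surface chain: vessel emphasis (3D median + square), Otsu extraction
#' of bright subdermal vessel voxels, per-slice maximum radii, spheroid fit,
#' then mask and depth-map construction.
#'
#' @param vol A [gridded_volume], typically the incident-compensated
#'   brightness.
#' @param n_bins Histogram bins for the Otsu threshold.
#' @return A `surface_estimate` (see [build_mask_and_depth()]) with the
#'   intermediate `slice_radii` table and `otsu_threshold` recorded.
#' @export
estimate_surface <- function(vol, n_bins = 256L) {
  emph <- vessel_emphasis(vol)
  t_otsu <- otsu_threshold(emph, n_bins = n_bins)
  v_set <- emph$data >= t_otsu
  radii <- slice_radii(v_set, vol)
  model <- fit_ellipse(radii)
  est <- build_mask_and_depth(model, vol)
  est$slice_radii <- radii
  est$otsu_threshold <- t_otsu
  est
}

#' @export
print.surface_estimate <- function(x, ...) {
  cat("<surface_estimate>\n  ")
  print(x$model)
  cat(sprintf("  mask voxels: %d\n", sum(x$mask$data > 0)))
  invisible(x)
}
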