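test_that("vessel emphasis squares the median-filtered volume", {
  v <- flat_volume(3, n = 9)
  expect_equal(vessel_emphasis(v)$data, array(9, c(9, 9, 9)))
  v2 <- flat_volume(0, n = 9)
  v2$data[5, 5, 5] <- 9                      # isolated voxel
  expect_equal(vessel_emphasis(v2)$data[5, 5, 5], 0)
  v3 <- flat_volume(2, n = 9)
  expect_equal(vessel_emphasis(v3)$data[4, 4, 4], 4)
})

test_that("otsu threshold separates a two-delta histogram and rejects constants", {
  v <- c(rep(0, 1000), rep(10, 1000))
  t0 <- otsu_threshold(v)
  expect_gt(t0, 0); expect_lte(t0, 10)
  expect_equal(sum(v >= t0), 1000)
  expect_error(otsu_threshold(rep(4, 100)), "degenerate-histogram")
})

test_that("otsu equals the exhaustive between-class-variance search", {
  set.seed(5)
  v <- c(rnorm(5e4, 20, 5), rnorm(5e4, 200, 5))
  t_fast <- otsu_threshold(v)
  t_brute <- brute_otsu(v)
  expect_equal(t_fast, t_brute)
  expect_gt(t_fast, 50); expect_lt(t_fast, 170)
})

test_that("slice radii match an exhaustive scan and flag empty slices", {
  set.seed(8)
  g <- gridded_volume(array(0, c(15, 15, 9)), 2)
  m <- array(runif(15 * 15 * 9) < 0.05, c(15, 15, 9))
  m[, , 4] <- FALSE
  sr <- slice_radii(m, g)
  rho <- radial_distance_map(g)
  for (j in 1:9) {
    sel <- m[, , j]
    if (!any(sel)) expect_true(is.na(sr$rho_mm[j]))
    else expect_equal(sr$rho_mm[j], max(rho[, , j][sel]))
  }
  expect_error(slice_radii(array(FALSE, c(3, 3, 3)),
                           gridded_volume(array(0, c(3, 3, 3)), 1)),
               "empty")
})

test_that("ellipse fit recovers exact and noisy generating parameters", {
  z <- seq(-44, 0, length.out = 20)
  truth <- list(a = 45, b = 55, zc = 0)
  rho <- truth$b * sqrt(1 - (z - truth$zc)^2 / truth$a^2)
  fit <- fit_ellipse(data.frame(z_mm = z, rho_mm = rho))
  expect_equal(fit$a_mm, truth$a, tolerance = 1e-6)
  expect_equal(fit$b_mm, truth$b, tolerance = 1e-6)
  expect_equal(fit$zc_mm, truth$zc, tolerance = 1e-5)

  circ <- 60 * sqrt(1 - z^2 / 60^2)
  cfit <- fit_ellipse(data.frame(z_mm = z, rho_mm = circ))
  expect_equal(cfit$a_mm, 60, tolerance = 1e-5)
  expect_equal(cfit$b_mm, 60, tolerance = 1e-5)

  set.seed(31)
  errs <- replicate(20, {
    noisy <- rho + runif(length(rho), -0.5, 0.5)
    f <- fit_ellipse(data.frame(z_mm = z, rho_mm = noisy))
    abs(c(f$a_mm - truth$a, f$b_mm - truth$b, f$zc_mm - truth$zc))
  })
  expect_lt(mean(errs), 1)
})

test_that("mask and depth follow the spheroid geometry", {
  g <- gridded_volume(array(0, c(41, 41, 41)), 3)  # coords -60..60
  est <- build_mask_and_depth(surface_model(60, 60, 0), g)
  at <- function(a, x, y, z) a[(x + 60) / 3 + 1, (y + 60) / 3 + 1,
                               (z + 60) / 3 + 1]
  expect_equal(at(est$mask$data, 0, 0, 0), 1)       # centre is inside
  expect_equal(at(est$mask$data, 0, 57, 57), 0)     # well outside
  expect_equal(at(est$depth$data, 0, 0, -30), 30)
  expect_true(is.na(at(est$depth$data, 60, 60, 60)))
})

test_that("mask volume is monotone in the semi-axes", {
  g <- gridded_volume(array(0, c(25, 25, 25)), 5)
  m1 <- build_mask_and_depth(surface_model(40, 50, 0), g)$mask$data
  m2 <- build_mask_and_depth(surface_model(48, 58, 0), g)$mask$data
  expect_true(all(m2[m1 > 0] > 0))
})

test_that("depth map is 1-Lipschitz across neighbouring voxels", {
  g <- gridded_volume(array(0, c(31, 31, 31)), 4)
  est <- build_mask_and_depth(surface_model(55, 60, 2), g)
  d <- est$depth$data
  step <- g$voxel_size_mm
  dx <- abs(d[-1, , ] - d[-31, , ])
  expect_true(all(dx[!is.na(dx)] <= step + 1e-9))
  dz <- abs(d[, , -1] - d[, , -31])
  expect_true(all(dz[!is.na(dz)] <= step + 1e-9))
})

test_that("end-to-end surface recovery on the phantom is within 2 voxels", {
  gt <- task_phantom()
  est <- task_normalization()$surface
  tolmm <- 2 * gt$spec$voxel_size_mm
  expect_lt(abs(est$model$a_mm - gt$surface_true$a_mm), tolmm)
  expect_lt(abs(est$model$b_mm - gt$surface_true$b_mm), tolmm)
  expect_lt(abs(est$model$zc_mm - gt$surface_true$zc_mm), tolmm)
})
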