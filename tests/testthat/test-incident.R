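test_that("angular MVBP picks the per-bin maximum", {
  v <- gridded_volume(array(0, c(41, 41, 41)), 2)  # coords -40..40
  # one bright voxel at theta ~ 120.3 deg: direction (sin th, 0, cos th)
  th0 <- 120.3 * pi / 180
  p <- round(c(30 * sin(th0), 0, 30 * cos(th0)) / 2) * 2
  i <- p / 2 + 21
  v$data[i[1], i[2], i[3]] <- 5
  th_p <- acos(p[3] / sqrt(sum(p^2))) * 180 / pi  # actual angle of that voxel
  mv <- angular_mvbp(v, polar_binning())
  hit <- mv$theta_deg[which(mv$max_brightness == 5)]
  expect_equal(hit, round(th_p))
})

test_that("constant volume fills every non-empty bin with the constant", {
  v <- gridded_volume(array(7, c(31, 31, 31)), 3)
  mv <- angular_mvbp(v)
  expect_true(all(mv$max_brightness[!is.na(mv$max_brightness)] == 7))
  expect_true(sum(!is.na(mv$max_brightness)) > 50)
})

test_that("MVBP agrees with an exhaustive per-voxel scan", {
  v <- gridded_volume(array(0, c(25, 25, 25)), 4)
  th <- polar_angle_map(v)
  v$data[] <- ifelse(is.na(th), 0, th)      # brightness = angle in degrees
  binning <- polar_binning()
  mv <- angular_mvbp(v, binning)
  idx <- assign_theta_bins(th, binning)
  for (b in seq_along(mv$theta_deg)) {
    sel <- !is.na(idx) & idx == b
    if (!any(sel)) expect_true(is.na(mv$max_brightness[b]))
    else expect_equal(mv$max_brightness[b], max(v$data[sel]))
  }
})

test_that("no voxels in range errors", {
  v <- gridded_volume(array(1, c(5, 5, 5)), 0.1,
                      origin_mm = c(0.05, 0.05, 0.05))  # all theta < 90
  expect_error(angular_mvbp(v), "no-voxels-in-range")
})

test_that("polynomial profile fit recovers exact generating coefficients", {
  th <- seq(90, 160, by = 1)
  lin <- data.frame(theta_deg = th, max_brightness = 2 - 0.01 * th)
  p1 <- fit_incident_profile(lin, 1)
  expect_equal(p1$coeffs, c(-0.01, 2), tolerance = 1e-9)
  cst <- data.frame(theta_deg = th, max_brightness = rep(5, length(th)))
  pc <- fit_incident_profile(cst, 1)
  expect_equal(pc$coeffs[1], 0, tolerance = 1e-12)
  quad <- data.frame(theta_deg = th,
                     max_brightness = 3 - 0.02 * th + 1e-4 * th^2)
  p2 <- fit_incident_profile(quad, 2)
  expect_equal(p2$coeffs, c(1e-4, -0.02, 3), tolerance = 1e-7)
})

test_that("compensation identities and gains", {
  v <- gridded_volume(array(10, c(21, 21, 21)), 3)
  cst <- data.frame(theta_deg = 90:160, max_brightness = rep(4, 71))
  prof <- fit_incident_profile(cst, 0)
  out <- compensate_incident(v, prof)
  expect_equal(out$data, v$data)            # constant profile: identity
  # profile value 0.5 at a known angle -> gain 2
  prof2 <- structure(list(coeffs = c(-0.5 / 70, 1 + 0.5 * 90 / 70),
                          degree_L = 1L, fit_range_deg = c(90, 160),
                          normalization = 1),
                     class = "incident_profile")
  expect_equal(eval_incident_profile(prof2, 160), 0.5)
  expect_equal(10 / eval_incident_profile(prof2, 160), 20)
})

test_that("profile evaluation clamps, floors, and unit-gains undefined angles", {
  prof <- structure(list(coeffs = c(-0.02, 2.8), degree_L = 1L,
                         fit_range_deg = c(90, 160), normalization = 1),
                    class = "incident_profile")
  expect_equal(eval_incident_profile(prof, 200), eval_incident_profile(prof, 160))
  expect_equal(eval_incident_profile(prof, 10), eval_incident_profile(prof, 90))
  deep <- structure(list(coeffs = c(-1, 90.5), degree_L = 1L,
                         fit_range_deg = c(90, 160), normalization = 1),
                    class = "incident_profile")
  expect_equal(eval_incident_profile(deep, 160), 0.05)  # floored
  expect_equal(eval_incident_profile(prof, NA), 1)
})

test_that("input scaling propagates linearly through the whole compensation", {
  gt <- coarse_phantom()
  v <- gt$p0[["800"]]
  vk <- gridded_volume(v$data * 3.7, v$voxel_size_mm, v$origin_mm)
  b <- polar_binning()
  m1 <- angular_mvbp(v, b); m2 <- angular_mvbp(vk, b)
  expect_equal(m2$max_brightness, 3.7 * m1$max_brightness)
  p1 <- fit_incident_profile(m1, 2); p2 <- fit_incident_profile(m2, 2)
  o1 <- compensate_incident(v, p1); o2 <- compensate_incident(vk, p2)
  expect_equal(o2$data, 3.7 * o1$data, tolerance = 1e-10)
})

test_that("polynomial brightness in theta is flattened by compensation", {
  v <- gridded_volume(array(0, c(41, 41, 41)), 2)
  th <- polar_angle_map(v)
  g <- 2 - 0.008 * pmin(160, pmax(90, ifelse(is.na(th), 90, th)))
  v$data[] <- g
  mv <- angular_mvbp(v)
  prof <- fit_incident_profile(mv, 1)
  out <- compensate_incident(v, prof)
  mv2 <- angular_mvbp(out)
  vals <- mv2$max_brightness[!is.na(mv2$max_brightness)]
  # flat up to the binning discretisation (per-bin max sits off-centre)
  expect_lt(diff(range(vals)) / mean(vals), 0.01)
  before <- mv$max_brightness[!is.na(mv$max_brightness)]
  expect_gt(diff(range(before)) / mean(before), 0.2)
})
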