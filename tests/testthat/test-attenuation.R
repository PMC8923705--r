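make_depth_fixture <- function(n = 21, voxel = 1) {
  g <- gridded_volume(array(0, c(n, n, n)), voxel)
  est <- build_mask_and_depth(surface_model(9 * voxel, 9 * voxel, 0), g)
  list(grid = g, est = est)
}

test_that("depth-binned max places values in the documented bins", {
  g <- gridded_volume(array(0, c(5, 5, 5)), 0.25)
  depth <- gridded_volume(array(NA_real_, c(5, 5, 5)), 0.25,
                          allow_na = TRUE)
  depth$data[3, 3, 3] <- 3.2
  g$data[3, 3, 3] <- 8
  tab <- depth_binned_max(g, depth, delta_d = 0.25)
  expect_equal(tab$max_brightness[13], 8)            # floor(3.2/0.25) = 12
  expect_equal(tab$depth_mm[13], 12.5 * 0.25)
  expect_true(all(is.na(tab$max_brightness[-13])))
})

test_that("monotone decay gives strictly decreasing bin maxima", {
  fx <- make_depth_fixture()
  v <- fx$grid
  d <- fx$est$depth$data
  v$data[!is.na(d)] <- 100 * exp(-0.1 * d[!is.na(d)])
  tab <- depth_binned_max(v, fx$est$depth, delta_d = 1)
  mx <- tab$max_brightness[!is.na(tab$max_brightness)]
  expect_true(all(diff(mx) < 0))
})

test_that("depth-binned max equals an exhaustive per-bin scan", {
  set.seed(12)
  fx <- make_depth_fixture()
  v <- fx$grid
  v$data[] <- rnorm(length(v$data))
  tab <- depth_binned_max(v, fx$est$depth, delta_d = 0.8)
  d <- fx$est$depth$data
  for (m in seq_len(nrow(tab))) {
    sel <- !is.na(d) & d >= (m - 1) * 0.8 & d < m * 0.8
    if (!any(sel)) expect_true(is.na(tab$max_brightness[m]))
    else expect_equal(tab$max_brightness[m], max(v$data[sel]))
  }
})

test_that("beer-lambert fit recovers exact, constant, and noisy decays", {
  d <- seq(0.5, 29.5, by = 1)
  ex <- data.frame(depth_mm = d, max_brightness = 100 * exp(-0.1 * d))
  fit <- fit_beer_lambert(ex)
  expect_equal(fit$c_star, 100, tolerance = 1e-8)
  expect_equal(fit$mu_eff_star, 0.1, tolerance = 1e-8)
  expect_equal(mu_eff_cm(fit), 1.0, tolerance = 1e-8)

  cst <- data.frame(depth_mm = d, max_brightness = rep(50, length(d)))
  fit0 <- fit_beer_lambert(cst)
  expect_equal(fit0$mu_eff_star, 0, tolerance = 1e-10)
  expect_equal(fit0$c_star, 50, tolerance = 1e-8)

  set.seed(77)
  d40 <- seq(0.5, 29.5, length.out = 40)
  rel_err <- replicate(50, {
    y <- 100 * exp(-0.1 * d40) * exp(rnorm(40, sd = 0.1))
    f <- fit_beer_lambert(data.frame(depth_mm = d40, max_brightness = y))
    abs(f$mu_eff_star - 0.1) / 0.1
  })
  expect_lt(median(rel_err), 0.1)
})

test_that("attenuation compensation gain and masking behave per the model", {
  fx <- make_depth_fixture()
  v <- fx$grid
  v$data[] <- 2
  m0 <- structure(list(c_star = 5, mu_eff_star = 0,
                       fit_depth_range_mm = c(0, 30), binned_max = NULL),
                  class = "attenuation_model")
  out0 <- compensate_attenuation(v, m0, fx$est)
  inmask <- fx$est$mask$data > 0
  expect_equal(out0$data[inmask], v$data[inmask])   # mu = 0: identity in-mask
  expect_true(all(out0$data[!inmask] == 0))         # zero outside

  mu <- log(4) / 5                                  # exp(-mu*5) = 0.25
  m1 <- structure(list(c_star = 1, mu_eff_star = mu,
                       fit_depth_range_mm = c(0, 30), binned_max = NULL),
                  class = "attenuation_model")
  out1 <- compensate_attenuation(v, m1, fx$est)
  d <- fx$est$depth$data
  probe <- which(!is.na(d) & abs(d - 5) < 1e-9)[1]
  skip_if(is.na(probe))
  expect_equal(out1$data[probe], 8)

  # gain is monotone non-decreasing in depth
  ord <- order(d[inmask])
  gains <- (out1$data[inmask] / v$data[inmask])[ord]
  expect_true(all(diff(gains) > -1e-12))
})

test_that("gain cap limits amplification beyond the cap depth", {
  fx <- make_depth_fixture(n = 41, voxel = 2)      # depths up to ~18mm
  v <- fx$grid; v$data[] <- 1
  m <- structure(list(c_star = 1, mu_eff_star = 0.5,
                      fit_depth_range_mm = c(0, 30), binned_max = NULL),
                 class = "attenuation_model")
  out <- compensate_attenuation(v, m, fx$est, depth_cap_mm = 10)
  inmask <- fx$est$mask$data > 0
  expect_lte(max(out$data[inmask]), exp(0.5 * 10) + 1e-9)
})

test_that("compensating a generated decay flattens the depth profile", {
  fx <- make_depth_fixture(n = 31, voxel = 2)
  v <- fx$grid
  d <- fx$est$depth$data
  v$data[!is.na(d)] <- 10 * exp(-0.12 * d[!is.na(d)])
  tab <- depth_binned_max(v, fx$est$depth, delta_d = 2)
  fit <- fit_beer_lambert(tab, fit_depth_range_mm = c(0, 30))
  out <- compensate_attenuation(v, fit, fx$est)
  tab2 <- depth_binned_max(out, fx$est$depth, delta_d = 2)
  mx <- tab2$max_brightness[!is.na(tab2$max_brightness)]
  expect_lt(diff(range(mx)) / mean(mx), 0.05)
})
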