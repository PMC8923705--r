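# Shared fixtures, built once per test run and cached.
# Sizes: unit tests use a coarse 2 mm phantom; the acceptance checks use a
# 1 mm fixture for task metrics and 0.5 mm phantoms for attenuation
# recovery (the voxel size the simulation studies use).

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_env)) assign(name, build(), .fixture_env)
  get(name, .fixture_env)
}

coarse_phantom <- function() fixture("coarse", function() {
  generate_phantom(phantom_spec(voxel_size_mm = 2, seed = 7,
                                n_vessel_segments = 20))
})

task_phantom <- function() fixture("task", function() {
  generate_phantom(phantom_spec(voxel_size_mm = 1, seed = 11))
})

task_normalization <- function() fixture("task_norm", function() {
  run_normalize(task_phantom()$p0, oat_config())
})

# small analytic volume helpers
flat_volume <- function(value = 0, n = 8, voxel = 1) {
  gridded_volume(array(value, dim = c(n, n, n)), voxel)
}

# brightness cylinder along a given axis through the volume centre
cylinder_volume <- function(n = 41, radius = 2, axis = 3, value = 1) {
  v <- array(0, dim = c(n, n, n))
  mid <- (n + 1) / 2
  ix <- slice.index(v, 1); iy <- slice.index(v, 2); iz <- slice.index(v, 3)
  perp <- switch(axis,
                 (iy - mid)^2 + (iz - mid)^2,
                 (ix - mid)^2 + (iz - mid)^2,
                 (ix - mid)^2 + (iy - mid)^2)
  v[perp <= radius^2] <- value
  gridded_volume(v, 1)
}

ball_volume <- function(n = 41, radius = 2, value = 1) {
  v <- array(0, dim = c(n, n, n))
  mid <- (n + 1) / 2
  ix <- slice.index(v, 1); iy <- slice.index(v, 2); iz <- slice.index(v, 3)
  v[(ix - mid)^2 + (iy - mid)^2 + (iz - mid)^2 <= radius^2] <- value
  gridded_volume(v, 1)
}

# brute-force minimum distance to a spheroid surface by dense sampling
brute_spheroid_depth <- function(p, surf, n = 200000L) {
  t <- seq(0, pi, length.out = n)
  rho <- sqrt(p[1]^2 + p[2]^2); u <- p[3] - surf$zc_mm
  min(sqrt((rho - surf$b_mm * sin(t))^2 + (u - surf$a_mm * cos(t))^2))
}

# exhaustive Otsu: try every histogram cut, maximise between-class variance
brute_otsu <- function(v, n_bins = 256L) {
  rng <- range(v)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  b <- pmin(n_bins, pmax(1L, findInterval(v, breaks, rightmost.closed = TRUE)))
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  sb <- rep(-Inf, n_bins - 1L)
  for (k in seq_len(n_bins - 1L)) {
    lo <- b <= k
    n0 <- sum(lo); n1 <- length(v) - n0
    if (n0 == 0 || n1 == 0) next
    m0 <- mean(mids[b[lo]]); m1 <- mean(mids[b[!lo]])
    sb[k] <- n0 / length(v) * n1 / length(v) * (m0 - m1)^2
  }
  best <- which(sb == max(sb))
  breaks[best[ceiling(length(best) / 2)] + 1L]
}
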