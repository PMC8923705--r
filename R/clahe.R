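#' 3D contrast limited adaptive histogram equalization (CLAHE)
#'
#' Volumetric extension of CLAHE, used as the general-purpose contrast
#' baseline against which fluence normalization is compared. The volume is
#' partitioned into a tile grid; each tile's histogram is clipped at
#' `clip_limit` times the tile voxel count with the clipped mass
#' redistributed uniformly, and its cumulative distribution defines a
#' mapping onto the input value range. Each voxel's output trilinearly
#' interpolates the mappings of the 8 surrounding tile centres, so tile
#' seams are invisible. The output range is contained in the input range,
#' and within a tile the mapping is monotone.
#'
#' @param vol A [gridded_volume].
#' @param tiles Integer length-3 tile grid (default `c(8, 8, 4)`).
#' @param clip_limit Histogram clip as a fraction of the tile voxel count,
#'   in (0, 1] (default 0.01).
#' @param n_bins Histogram bins (default 256).
#' @return A [gridded_volume] on the same grid.
#' @export
clahe_3d <- function(vol, tiles = c(8, 8, 4), clip_limit = 0.01,
                     n_bins = 256L) {
  stopifnot(length(tiles) == 3, all(tiles >= 1),
            clip_limit > 0, clip_limit <= 1, n_bins >= 2)
  v <- vol$data
  d <- dim(v)
  rng <- range(v)
  if (diff(rng) == 0) return(vol)           # constant: nothing to equalize
  bin <- pmin(n_bins, pmax(1L, floor((v - rng[1]) / diff(rng) * n_bins) + 1L))

  # tile index per axis (equal partitions; last tile absorbs the remainder)
  tix <- lapply(1:3, function(ax) {
    pmin(tiles[ax], floor((seq_len(d[ax]) - 1) / d[ax] * tiles[ax]) + 1L)
  })
  tx <- tix[[1]][slice.index(v, 1)]
  ty <- tix[[2]][slice.index(v, 2)]
  tz <- tix[[3]][slice.index(v, 3)]
  tile_id <- tx + tiles[1] * (ty - 1L) + tiles[1] * tiles[2] * (tz - 1L)
  n_tiles <- prod(tiles)

  counts <- tabulate((tile_id - 1L) * n_bins + bin, nbins = n_tiles * n_bins)
  counts <- matrix(counts, nrow = n_bins, ncol = n_tiles)
  tile_n <- colSums(counts)
  limit <- pmax(1, clip_limit * tile_n)
  clipped <- pmin(counts, rep(limit, each = n_bins))
  excess <- tile_n - colSums(clipped)
  clipped <- clipped + rep(excess / n_bins, each = n_bins)
  cdf <- apply(clipped, 2, cumsum)
  # map bin -> value in the input range
  mapping <- rng[1] + diff(rng) * sweep(cdf, 2, pmax(tile_n, 1), "/")

  # tile centres (in voxel index units) for trilinear interpolation
  centers <- lapply(1:3, function(ax) {
    vapply(seq_len(tiles[ax]), function(t) mean(which(tix[[ax]] == t)),
           numeric(1))
  })
  frac <- function(ax) {
    cc <- centers[[ax]]
    pos <- as.numeric(slice.index(v, ax))
    lo <- pmin(length(cc) - 1L, pmax(1L, findInterval(pos, cc)))
    if (length(cc) == 1L) return(list(lo = rep(1L, length(pos)),
                                      w = rep(0, length(pos))))
    w <- (pos - cc[lo]) / (cc[lo + 1L] - cc[lo])
    list(lo = lo, w = pmin(1, pmax(0, w)))
  }
  fx <- frac(1); fy <- frac(2); fz <- frac(3)

  b <- as.vector(bin)
  gather <- function(ix, iy, iz) {
    tid <- ix + tiles[1] * (iy - 1L) + tiles[1] * tiles[2] * (iz - 1L)
    mapping[cbind(b, tid)]
  }
  hx <- pmin(tiles[1], fx$lo + 1L); hy <- pmin(tiles[2], fy$lo + 1L)
  hz <- pmin(tiles[3], fz$lo + 1L)
  wx <- fx$w; wy <- fy$w; wz <- fz$w
  out <-
    (1 - wx) * (1 - wy) * (1 - wz) * gather(fx$lo, fy$lo, fz$lo) +
    wx       * (1 - wy) * (1 - wz) * gather(hx,    fy$lo, fz$lo) +
    (1 - wx) * wy       * (1 - wz) * gather(fx$lo, hy,    fz$lo) +
    wx       * wy       * (1 - wz) * gather(hx,    hy,    fz$lo) +
    (1 - wx) * (1 - wy) * wz       * gather(fx$lo, fy$lo, hz) +
    wx       * (1 - wy) * wz       * gather(hx,    fy$lo, hz) +
    (1 - wx) * wy       * wz       * gather(fx$lo, hy,    hz) +
    wx       * wy       * wz       * gather(hx,    hy,    hz)
  with_data(vol, array(out, dim = d))
}
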