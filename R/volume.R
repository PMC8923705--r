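#' Gridded 3D volume
#'
#' A scalar field on a uniform Cartesian lattice with a physical voxel size
#' and world origin. This is the container for every volumetric quantity in
#' the package: reconstructed optoacoustic brightness, fluence estimates,
#' absorption coefficients, vesselness, oxygen-saturation maps, masks, and
#' depth maps. World coordinates are millimetres; the world coordinate of
#' voxel `(i, j, k)` (1-based indices) is
#' `origin_mm + voxel_size_mm * (i - 1, j - 1, k - 1)` (voxel-centre
#' convention).
#'
#' The package's coordinate convention places the origin at the centre of the
#' breast stabilizer cup with the z axis pointing up: the breast occupies
#' z < 0, the chest wall lies in the plane of polar angle 90 degrees, and the
#' nipple pole is at 180 degrees.
#'
#' @param data Numeric 3D array. `NA` is allowed only where a map is
#'   deliberately undefined (e.g. masked sO2); otherwise values must be finite.
#' @param voxel_size_mm Positive scalar, isotropic voxel edge length in mm.
#' @param origin_mm Numeric length-3 vector, world coordinate (mm) of the
#'   centre of voxel `(1, 1, 1)`. Default centres the grid on the world
#'   origin.
#' @param allow_na Logical, permit `NA` voxels (used by masked maps).
#' @return An object of class `gridded_volume`.
#' @export
gridded_volume <- function(data, voxel_size_mm, origin_mm = NULL,
                           allow_na = FALSE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L ||
      !is.finite(voxel_size_mm) || voxel_size_mm <= 0)
    stop("`voxel_size_mm` must be a positive scalar", call. = FALSE)
  if (is.null(origin_mm))
    origin_mm <- -voxel_size_mm * (dim(data) - 1) / 2
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("`origin_mm` must be a finite length-3 vector", call. = FALSE)
  if (!allow_na && anyNA(data))
    stop("`data` contains non-finite values", call. = FALSE)
  storage.mode(data) <- "double"
  structure(
    list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
         origin_mm = as.numeric(origin_mm)),
    class = "gridded_volume"
  )
}

#' @export
print.gridded_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<gridded_volume> %d x %d x %d voxels @ %.4g mm\n",
              d[1], d[2], d[3], x$voxel_size_mm))
  cat(sprintf("  origin (mm): [%.3f, %.3f, %.3f]\n",
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3]))
  rng <- range(x$data, na.rm = TRUE)
  cat(sprintf("  value range: [%.4g, %.4g]%s\n", rng[1], rng[2],
              if (anyNA(x$data)) sprintf(", %d NA", sum(is.na(x$data))) else ""))
  invisible(x)
}

#' @export
as.array.gridded_volume <- function(x, ...) x$data

#' @rdname gridded_volume
#' @param x Object to test.
#' @export
is_gridded_volume <- function(x) inherits(x, "gridded_volume")

# new volume on the same grid
with_data <- function(vol, data, allow_na = FALSE) {
  gridded_volume(data, vol$voxel_size_mm, vol$origin_mm, allow_na = allow_na)
}

assert_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)) ||
      !isTRUE(all.equal(a$voxel_size_mm, b$voxel_size_mm)) ||
      !isTRUE(all.equal(a$origin_mm, b$origin_mm)))
    stop("volumes are not on the same grid", call. = FALSE)
  invisible(TRUE)
}

#' Axis coordinates of a volume
#'
#' World coordinates (mm) of voxel centres along each axis.
#'
#' @param vol A [gridded_volume].
#' @return List with numeric vectors `x`, `y`, `z`.
#' @export
axis_coords <- function(vol) {
  d <- dim(vol$data)
  list(
    x = vol$origin_mm[1] + vol$voxel_size_mm * (seq_len(d[1]) - 1),
    y = vol$origin_mm[2] + vol$voxel_size_mm * (seq_len(d[2]) - 1),
    z = vol$origin_mm[3] + vol$voxel_size_mm * (seq_len(d[3]) - 1)
  )
}

# per-voxel world coordinate arrays, built lazily where needed
coord_array <- function(vol, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  d <- dim(vol$data)
  cc <- axis_coords(vol)[[axis]]
  switch(axis,
    x = array(cc, dim = d),
    y = array(rep(cc, each = d[1]), dim = d),
    z = array(rep(cc, each = d[1] * d[2]), dim = d)
  )
}

#' Read and write volumes
#'
#' Volumes are exchanged either as NIfTI (`.nii`/`.nii.gz`, voxel size and
#' origin taken from the sform) or as raw little-endian float32 with a JSON
#' sidecar holding `shape`, `voxel_size_mm` and `origin_mm`. The sidecar path
#' is `<file>.json` next to the `.raw` file.
#'
#' @param vol A [gridded_volume].
#' @param path Output file; format chosen from the extension
#'   (`.nii`, `.nii.gz`, or `.raw`).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   [gridded_volume].
#' @export
write_volume <- function(vol, path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(vol$data)
    aff <- diag(c(rep(vol$voxel_size_mm, 3), 1))
    aff[1:3, 4] <- vol$origin_mm
    RNifti::sform(img) <- structure(aff, code = 2L)
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.raw$", path)) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.vector(vol$data), con, size = 4L, endian = "little")
    meta <- list(shape = dim(vol$data), voxel_size_mm = vol$voxel_size_mm,
                 origin_mm = vol$origin_mm, dtype = "float32",
                 byte_order = "little")
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else stop("unrecognised volume extension: ", path, call. = FALSE)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    aff <- RNifti::xform(img)
    vx <- abs(aff[1, 1])
    # RNifti may flip axis signs on canonicalisation; undo for the origin
    origin <- aff[1:3, 4] * sign(diag(aff)[1:3])
    gridded_volume(array(as.numeric(img), dim = dim(img)), vx, origin,
                   allow_na = TRUE)
  } else if (grepl("\\.raw$", path)) {
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    n <- prod(meta$shape)
    con <- file(path, "rb")
    on.exit(close(con))
    v <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
    gridded_volume(array(v, dim = meta$shape), meta$voxel_size_mm,
                   meta$origin_mm, allow_na = TRUE)
  } else stop("unrecognised volume extension: ", path, call. = FALSE)
}
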