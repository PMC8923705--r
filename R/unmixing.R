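#' Molar extinction coefficient table
#'
#' Wavelength-indexed molar extinction coefficients of deoxyhemoglobin (Hb)
#' and oxyhemoglobin (HbO2), in consistent units (the bundled table uses
#' cm^-1/M). At least two wavelengths are required and the n x 2 matrix must
#' have rank 2 (an extinction matrix whose two columns are proportional
#' cannot separate the chromophores).
#'
#' @param wavelengths_nm Numeric vector of wavelengths.
#' @param eps_hb,eps_hbo2 Extinction coefficients per wavelength.
#' @return An object of class `extinction_table`.
#' @export
extinction_table <- function(wavelengths_nm, eps_hb, eps_hbo2) {
  stopifnot(length(wavelengths_nm) >= 2,
            length(eps_hb) == length(wavelengths_nm),
            length(eps_hbo2) == length(wavelengths_nm))
  E <- cbind(eps_hb, eps_hbo2)
  if (qr(E)$rank < 2)
    stop("degenerate-extinction: matrix must have rank 2", call. = FALSE)
  structure(list(wavelengths_nm = as.numeric(wavelengths_nm),
                 eps_hb = as.numeric(eps_hb),
                 eps_hbo2 = as.numeric(eps_hbo2)),
            class = "extinction_table")
}

#' @rdname extinction_table
#' @param path CSV with columns `wavelength_nm`, `eps_hb`, `eps_hbo2`.
#' @export
read_extinction <- function(path) {
  df <- read.csv(path)
  extinction_table(df$wavelength_nm, df$eps_hb, df$eps_hbo2)
}

#' Bundled hemoglobin extinction coefficients
#'
#' A compact table of molar extinction coefficients (cm^-1/M) of deoxy- and
#' oxyhemoglobin over 650-1000 nm, compiled from standard published
#' tabulations (values approximate; linear interpolation between tabulated
#' wavelengths). Concentrations unmixed with this table are in arbitrary
#' units unless the input volumes are calibrated absorption coefficients;
#' oxygen saturation, being a ratio, is unaffected.
#'
#' @param wavelengths_nm Wavelengths to extract (default 757, 800, 850 nm:
#'   a deoxyhemoglobin-weighted band, the isosbestic point, and an
#'   oxyhemoglobin-weighted band).
#' @return An [extinction_table].
#' @export
hb_extinction <- function(wavelengths_nm = c(757, 800, 850)) {
  lk <- hb_extinction_lookup(wavelengths_nm)
  extinction_table(wavelengths_nm, lk$eps_hb, lk$eps_hbo2)
}

# interpolated bundled extinction values without the rank-2 table contract
# (usable for a single wavelength, e.g. when simulating one-wavelength data)
hb_extinction_lookup <- function(wavelengths_nm) {
  path <- system.file("extdata", "hb_extinction.csv", package = "oatnorm",
                      mustWork = TRUE)
  df <- read.csv(path)
  if (any(wavelengths_nm < min(df$wavelength_nm) |
          wavelengths_nm > max(df$wavelength_nm)))
    stop("requested wavelength outside the bundled 650-1000 nm range",
         call. = FALSE)
  data.frame(
    wavelength_nm = wavelengths_nm,
    eps_hb = approx(df$wavelength_nm, df$eps_hb, xout = wavelengths_nm)$y,
    eps_hbo2 = approx(df$wavelength_nm, df$eps_hbo2, xout = wavelengths_nm)$y)
}

#' Spectral linear unmixing into hemoglobin concentrations
#'
#' Per-voxel least-squares solution of the linear spectral model: the vector
#' of per-wavelength brightness values (surrogates of the absorption
#' coefficient) is multiplied by the pseudoinverse of the extinction matrix,
#' giving deoxy- and oxyhemoglobin concentrations and their sum, the total
#' hemoglobin concentration. Negative concentrations are retained (no
#' nonnegativity constraint is imposed).
#'
#' @param vols Named or ordered list of [gridded_volume]s, one per
#'   wavelength, on identical grids, in the order of `table$wavelengths_nm`.
#' @param table An [extinction_table].
#' @return An object of class `chromophore_maps` with [gridded_volume]
#'   fields `c_hb`, `c_hbo2`, `c_thb`.
#' @export
unmix <- function(vols, table) {
  n <- length(vols)
  if (n < 2 || n != length(table$wavelengths_nm))
    stop("need one volume per table wavelength (>= 2)", call. = FALSE)
  for (i in seq_len(n)[-1]) assert_same_grid(vols[[1]], vols[[i]])
  E <- cbind(table$eps_hb, table$eps_hbo2)
  meas <- do.call(rbind, lapply(vols, function(v) as.vector(v$data)))
  cf <- qr.coef(qr(E), meas)                     # 2 x n_voxels
  d <- dim(vols[[1]]$data)
  c_hb <- with_data(vols[[1]], array(cf[1, ], dim = d))
  c_hbo2 <- with_data(vols[[1]], array(cf[2, ], dim = d))
  structure(list(c_hb = c_hb, c_hbo2 = c_hbo2,
                 c_thb = with_data(vols[[1]], c_hb$data + c_hbo2$data)),
            class = "chromophore_maps")
}

#' Oxygen saturation map
#'
#' `sO2 = 100 * C_HbO2 / CtHb` (percent) where the total hemoglobin
#' concentration exceeds `thb_floor`; elsewhere the map is undefined (`NA`).
#' The default floor is 1e-3 times a robust maximum (99.9th percentile) of
#' CtHb, masking voxels where the ratio would be dominated by noise.
#'
#' @param maps A `chromophore_maps` object from [unmix()].
#' @param thb_floor Positive scalar; `NULL` for the default.
#' @return A [gridded_volume] of sO2 in percent, `NA`-masked.
#' @export
so2_map <- function(maps, thb_floor = NULL) {
  thb <- maps$c_thb$data
  if (is.null(thb_floor))
    thb_floor <- 1e-3 * quantile(thb, 0.999, na.rm = TRUE, names = FALSE)
  so2 <- 100 * maps$c_hbo2$data / thb
  so2[!(thb > thb_floor)] <- NA_real_
  with_data(maps$c_thb, so2, allow_na = TRUE)
}
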