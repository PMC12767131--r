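#' Molar extinction table for hemoglobin
#'
#' Holds the molar extinction coefficients of oxy- and deoxyhemoglobin at
#' the acquisition wavelengths, the per-voxel design matrix of the
#' least-squares unmixing system `eps %*% C = PA`. The two spectra must not
#' be proportional (full column rank) and at least two wavelengths are
#' required.
#'
#' @param wavelengths Wavelengths in nm.
#' @param eps_hbo,eps_hbr Extinction coefficients (cm^-1 M^-1) per wavelength.
#' @return An object of class `extinction_table`.
#' @export
extinction_table <- function(wavelengths, eps_hbo, eps_hbr) {
  assert_that(length(wavelengths) >= 2, "at least two wavelengths required")
  assert_that(length(eps_hbo) == length(wavelengths) &&
              length(eps_hbr) == length(wavelengths),
              "epsilon lengths must match wavelengths")
  E <- cbind(HbO = eps_hbo, HbR = eps_hbr)
  assert_that(qr(E)$rank == 2, "HbO and HbR spectra must not be proportional")
  structure(list(wavelengths = as.numeric(wavelengths), epsilon = E),
            class = "extinction_table")
}

#' Default extinction table (730/756/796/866 nm)
#'
#' Values interpolated from the standard tabulated hemoglobin spectra
#' compilation; shipped as `inst/extdata/hb_extinction.csv`. Quantitative
#' tests synthesise their own coefficients, so no result depends on these
#' literature numbers.
#'
#' @return An [extinction_table()].
#' @export
default_extinction_table <- function() {
  path <- system.file("extdata", "hb_extinction.csv", package = "hdpact")
  tb <- read.csv(path)
  extinction_table(tb$wavelength_nm, tb$eps_hbo, tb$eps_hbr)
}

#' Least-squares spectral unmixing
#'
#' Recovers per-voxel oxy/deoxyhemoglobin concentrations from co-registered
#' multi-wavelength volumes by solving `eps %*% C = PA` in the least-squares
#' sense at every voxel. Preprocessing follows the standard pipeline: an
#' optional 3 x 3 x 3 median filter, then per-wavelength division by the
#' measured laser power. Negative solutions are clamped to zero and recorded
#' in the validity mask.
#'
#' @param volumes List of [volume_image()]s (or 3D arrays), one per
#'   wavelength, identical grids.
#' @param table An [extinction_table()] whose rows match `volumes`.
#' @param laser_powers Optional per-wavelength scalars; volumes are divided
#'   by these before unmixing.
#' @param prefilter Apply the 3 x 3 x 3 median filter (default TRUE).
#' @return An object of class `chromophore_maps` with `C_HbO`, `C_HbR`
#'   (arrays), and `clamped` (logical array: voxels where a negative
#'   solution was clamped). Derive sO2/HbT with [compute_so2_hbt()].
#' @export
lsq_unmix <- function(volumes, table, laser_powers = NULL, prefilter = TRUE) {
  assert_that(inherits(table, "extinction_table"),
              "table must be an extinction_table")
  arrs <- lapply(volumes, function(v)
    if (inherits(v, "volume_image")) v$voxels else v)
  W <- length(arrs)
  assert_that(W == length(table$wavelengths),
              "number of volumes must match table wavelengths")
  d <- dim(arrs[[1]])
  for (a in arrs) assert_that(all(dim(a) == d), "volumes must share one grid")
  if (!is.null(laser_powers)) {
    assert_that(length(laser_powers) == W && all(laser_powers > 0),
                "laser_powers must be positive, one per wavelength")
  }
  PA <- matrix(0, prod(d), W)
  for (k in seq_len(W)) {
    a <- arrs[[k]]
    if (prefilter) a <- median_filter3(a)
    if (!is.null(laser_powers)) a <- a / laser_powers[k]
    PA[, k] <- as.vector(a)
  }
  E <- table$epsilon
  # normal-equations pseudoinverse applied to all voxels at once
  Cmat <- PA %*% E %*% solve(crossprod(E))
  clamped <- Cmat < 0
  Cmat[clamped] <- 0
  structure(list(
    C_HbO = array(Cmat[, 1], d),
    C_HbR = array(Cmat[, 2], d),
    clamped = array(clamped[, 1] | clamped[, 2], d)
  ), class = "chromophore_maps")
}

# 3x3x3 voxelwise median with edge replication.
median_filter3 <- function(a) {
  d <- dim(a)
  offs <- expand.grid(i = -1:1, j = -1:1, k = -1:1)
  stack <- matrix(0, prod(d), nrow(offs))
  cl <- function(idx, n) pmin(pmax(idx, 1L), n)
  for (m in seq_len(nrow(offs))) {
    stack[, m] <- as.vector(a[cl(seq_len(d[1]) + offs$i[m], d[1]),
                              cl(seq_len(d[2]) + offs$j[m], d[2]),
                              cl(seq_len(d[3]) + offs$k[m], d[3])])
  }
  # median of 27 values = 14th order statistic, via one partial sort per row
  med <- apply(stack, 1, function(r) sort.int(r, partial = 14L)[14L])
  array(med, d)
}

#' Oxygen saturation and total hemoglobin
#'
#' `sO2 = C_HbO / (C_HbO + C_HbR)` and `C_HbT = C_HbO + C_HbR`, with sO2
#' masked invalid wherever total hemoglobin does not exceed `hbt_floor`
#' (guarding the 0/0 case and meaningless ratios in signal-free voxels).
#'
#' @param maps A [lsq_unmix()] result.
#' @param hbt_floor Validity threshold on `C_HbT`; default 1% of its maximum.
#' @return `maps` extended with `sO2` (NA where invalid), `C_HbT` and the
#'   logical `valid` mask.
#' @export
compute_so2_hbt <- function(maps, hbt_floor = NULL) {
  assert_that(inherits(maps, "chromophore_maps"),
              "maps must come from lsq_unmix")
  assert_that(all(maps$C_HbO >= 0) && all(maps$C_HbR >= 0),
              "concentrations must be non-negative")
  hbt <- maps$C_HbO + maps$C_HbR
  if (is.null(hbt_floor)) hbt_floor <- 0.01 * max(hbt)
  valid <- hbt > hbt_floor
  so2 <- array(NA_real_, dim(hbt))
  so2[valid] <- maps$C_HbO[valid] / hbt[valid]
  maps$sO2 <- so2
  maps$C_HbT <- hbt
  maps$valid <- valid
  maps$hbt_floor <- hbt_floor
  maps
}

#' @exportS3Method base::print
print.chromophore_maps <- function(x, ...) {
  d <- dim(x$C_HbO)
  cat(sprintf("<chromophore_maps> %s voxels%s\n",
              paste(d, collapse = " x "),
              if (!is.null(x$sO2))
                sprintf(", median sO2 %.3f over %d valid voxels",
                        median(x$sO2[x$valid]), sum(x$valid)) else ""))
  invisible(x)
}
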