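#' Peak signal-to-noise ratio
#'
#' `PSNR(x, y) = 10 log10(MAX^2 / MSE(x, y))` in dB. The data range `MAX`
#' defaults to 1 (volumes in this package are normalised to `[0, 1]`).
#' Identical inputs have zero MSE; the function then returns `Inf` with
#' attribute `zero_mse = TRUE` rather than failing.
#'
#' @param x,y Numeric arrays of identical shape.
#' @param max_value Data range `MAX`.
#' @return PSNR in dB (scalar).
#' @export
psnr <- function(x, y, max_value = 1) {
  assert_that(all(dim(x) %||% length(x) == dim(y) %||% length(y)),
              "x and y shapes must match")
  mse <- mean((x - y)^2)
  if (mse == 0) return(structure(Inf, zero_mse = TRUE))
  10 * log10(max_value^2 / mse)
}

#' Structural similarity index
#'
#' `SSIM(x, y) = (2 mu_x mu_y + C1)(2 sigma_xy + C2) /
#'   ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))`.
#' The default contract is the global-statistics form (one mean/variance/
#' covariance per image). A sliding-window variant (`window > 0`: uniform
#' `window x window` filter, unbiased variance, mean over the valid region)
#' is available for comparison with common reference implementations.
#'
#' @param x,y Numeric matrices/arrays of identical shape.
#' @param C1,C2 Stabilisation constants; defaults `(0.01 MAX)^2`,
#'   `(0.03 MAX)^2`.
#' @param max_value Data range used for the default constants.
#' @param window 0 for the global form (default), or an odd window size.
#' @return SSIM (scalar in `[-1, 1]`).
#' @export
ssim <- function(x, y, C1 = (0.01 * max_value)^2, C2 = (0.03 * max_value)^2,
                 max_value = 1, window = 0) {
  assert_that(all(dim(x) %||% length(x) == dim(y) %||% length(y)),
              "x and y shapes must match")
  assert_that(C1 > 0 && C2 > 0, "C1 and C2 must be positive")
  if (window > 0) return(ssim_windowed(as.matrix(x), as.matrix(y), C1, C2, window))
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

# Uniform-window SSIM: local means by box filter, unbiased local
# (co)variances, mean of the SSIM map over the fully-covered region.
ssim_windowed <- function(x, y, C1, C2, win) {
  assert_that(win %% 2 == 1 && win >= 3, "window must be odd and >= 3")
  n <- win^2
  box <- function(m) box_filter(m, win)
  ux <- box(x); uy <- box(y)
  cov_norm <- n / (n - 1)
  vx <- cov_norm * (box(x * x) - ux^2)
  vy <- cov_norm * (box(y * y) - uy^2)
  cxy <- cov_norm * (box(x * y) - ux * uy)
  s <- ((2 * ux * uy + C1) * (2 * cxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  pad <- (win - 1) / 2
  mean(s[(pad + 1):(nrow(s) - pad), (pad + 1):(ncol(s) - pad)])
}

# win x win moving average with zero padding (only the valid interior is
# consumed by the caller).
box_filter <- function(m, win) {
  pad <- (win - 1) / 2
  w <- matrix(1 / win^2, win * win, 1)
  arr <- array(m, c(dim(m), 1))
  .conv2d_fwd(arr, w, 0, win, win, 1L, pad)[, , 1]
}

#' Per-slice and overall restoration metrics
#'
#' Computes PSNR and global SSIM between a predicted and a reference volume,
#' per axial slice and overall.
#'
#' @param pred,ref [volume_image()]s (or bare 3D arrays) of identical shape.
#' @param max_value Data range.
#' @return A list of class `metric_report`: `psnr`, `ssim` (overall) and a
#'   `per_slice` data frame.
#' @export
metric_report <- function(pred, ref, max_value = 1) {
  p <- if (inherits(pred, "volume_image")) pred$voxels else pred
  r <- if (inherits(ref, "volume_image")) ref$voxels else ref
  assert_that(all(dim(p) == dim(r)), "volume shapes must match")
  nz <- dim(p)[3]
  per <- data.frame(
    slice = seq_len(nz),
    psnr = vapply(seq_len(nz), function(k) as.numeric(psnr(p[, , k], r[, , k], max_value)), 0),
    ssim = vapply(seq_len(nz), function(k) ssim(p[, , k], r[, , k], max_value = max_value), 0)
  )
  structure(list(psnr = as.numeric(psnr(p, r, max_value)),
                 ssim = ssim(p, r, max_value = max_value),
                 per_slice = per),
            class = "metric_report")
}

#' @exportS3Method base::print
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> PSNR %.2f dB, SSIM %.4f (%d slices)\n",
              x$psnr, x$ssim, nrow(x$per_slice)))
  invisible(x)
}
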