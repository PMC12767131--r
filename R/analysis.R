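#' Maximum amplitude projection
#'
#' Per-pixel maximum of a volume along one axis. In `"depth_encoded"` mode
#' the argmax depth index is returned alongside, for hue-coded depth maps;
#' ties resolve to the first (shallowest) index.
#'
#' @param volume A [volume_image()] or 3D array.
#' @param axis Projection axis (1, 2 or 3; default 3, the depth axis).
#' @param mode `"map"` or `"depth_encoded"`.
#' @return `"map"`: the 2D projection matrix. `"depth_encoded"`: a list with
#'   `map` and integer `depth`.
#' @export
max_projection <- function(volume, axis = 3, mode = c("map", "depth_encoded")) {
  mode <- match.arg(mode)
  v <- if (inherits(volume, "volume_image")) volume$voxels else volume
  assert_that(axis %in% 1:3, "axis must be 1, 2 or 3")
  m <- apply(v, setdiff(1:3, axis), max)
  if (mode == "map") return(m)
  idx <- apply(v, setdiff(1:3, axis), which.max)
  list(map = m, depth = idx)
}

#' Vessel density and mean HbT inside an ROI
#'
#' Segments vessels inside the region of interest by thresholding the HbT
#' (or amplitude) map and reports the vessel-area fraction
#' `density = vessel area / ROI area` and the mean map value over the
#' segmented vessel voxels. The default threshold is Otsu's rule on the ROI
#' histogram (parameter-free); a fixed-quantile rule is selectable.
#'
#' @param hbt_map 2D matrix (e.g. a [max_projection()]) or 3D array.
#' @param roi Logical mask, same shape; must contain at least one voxel.
#' @param threshold_rule `"otsu"`, `"quantile"` or `"fixed"`.
#' @param quantile Quantile used when `threshold_rule = "quantile"`.
#' @param threshold Absolute threshold used when `threshold_rule = "fixed"`.
#' @return List with `density`, `mean_hbt` (NA with `empty = TRUE` when no
#'   voxel is segmented), `threshold` and the logical `segmentation`.
#' @export
vessel_density <- function(hbt_map, roi,
                           threshold_rule = c("otsu", "quantile", "fixed"),
                           quantile = 0.75, threshold = NULL) {
  threshold_rule <- match.arg(threshold_rule)
  v <- if (inherits(hbt_map, "volume_image")) hbt_map$voxels else hbt_map
  assert_that(all(dim(v) == dim(roi)), "roi shape must match map")
  assert_that(any(roi), "roi must contain at least one voxel")
  vals <- v[roi]
  thr <- switch(threshold_rule,
    otsu = otsu_threshold(vals),
    quantile = stats::quantile(vals, quantile, names = FALSE),
    fixed = {
      assert_that(is.numeric(threshold), "fixed rule needs a threshold")
      threshold
    })
  seg <- roi & (v > thr)
  nseg <- sum(seg)
  list(density = nseg / sum(roi),
       mean_hbt = if (nseg > 0) mean(v[seg]) else NA_real_,
       empty = nseg == 0,
       threshold = thr,
       segmentation = seg)
}

# Otsu's threshold on a 256-bin histogram: maximise between-class variance.
otsu_threshold <- function(x, n_bins = 256) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_tot <- mu0[n_bins]
  w1 <- 1 - w0
  between <- (mu_tot * w0 - mu0)^2 / (w0 * w1)
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# Full width at half maximum of a 1D profile, in samples, with linear
# interpolation of the half-maximum crossings around the global peak.
profile_fwhm <- function(profile) {
  p <- abs(profile)
  pk <- which.max(p)
  half <- p[pk] / 2
  left <- pk
  while (left > 1 && p[left - 1] >= half) left <- left - 1
  lx <- if (left == 1) 1 else {
    (left - 1) + (half - p[left - 1]) / (p[left] - p[left - 1])
  }
  right <- pk
  n <- length(p)
  while (right < n && p[right + 1] >= half) right <- right + 1
  rx <- if (right == n) n else {
    right + (p[right] - half) / (p[right] - p[right + 1])
  }
  rx - lx
}

# Blur measure for point-spread checks: equivalent diameter (in voxels) of
# the half-maximum region on the axial slice through the global peak.
psf_fwhm_diameter <- function(vol) {
  v <- if (inherits(vol, "volume_image")) vol$voxels else vol
  pk <- arrayInd(which.max(abs(v)), dim(v))
  sl <- abs(v[, , pk[3]])
  2 * sqrt(sum(sl >= max(sl) / 2) / pi)
}

#' High-frequency band energy of a slice
#'
#' Total spectral power at radial frequencies above `frac` times the slice
#' size (unitary-normalised 2D FFT). Used to quantify artifact character:
#' radial streaks concentrate energy in this band, blur removes it.
#'
#' @param slice 2D matrix (square).
#' @param frac Radial cutoff as a fraction of the grid size.
#' @return Scalar band energy.
#' @export
hf_band_energy <- function(slice, frac = 0.25) {
  n <- nrow(slice)
  sp <- Mod(fft(slice) / n)^2
  ci <- (seq_len(n) - 1) - floor(n / 2)
  rr <- ifftshift2(sqrt(outer(ci^2, ci^2, "+")))
  sum(sp[rr > n * frac])
}

#' Signed high-frequency energy shift of a degraded slice
#'
#' Fits a single gain `a = <d, f> / <d, d>` aligning the degraded slice `d`
#' to the reference `f` (sub-aperture reconstructions are systematically
#' dimmer), then reports the change in high-frequency band energy
#' `hf(a * d) - hf(f)`. Positive values mean the degradation *added*
#' high-frequency content (streak artifacts of sparse sampling), negative
#' values mean it *removed* it (blur of cluster sampling).
#'
#' @param full Reference slice (full-array reconstruction).
#' @param degraded Degraded slice (subsampled reconstruction), same shape.
#' @param frac Radial cutoff, see [hf_band_energy()].
#' @return Scalar energy shift (same units as [hf_band_energy()]).
#' @export
artifact_spectral_shift <- function(full, degraded, frac = 0.25) {
  assert_that(all(dim(full) == dim(degraded)), "slice shapes must match")
  a <- sum(degraded * full) / max(sum(degraded^2), 1e-12)
  hf_band_energy(a * degraded, frac) - hf_band_energy(full, frac)
}
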