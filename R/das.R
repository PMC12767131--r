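#' Delay-and-sum reconstruction
#'
#' Back-projects each channel onto the grid: a voxel's value is the sum over
#' channels of the sample at the one-way time of flight
#' `|p_elem - p_voxel| / c`, linearly interpolated between samples. The
#' operation is linear in the RF frame. Voxels whose time of flight falls
#' outside the recorded window contribute zero (a warning reports how many).
#'
#' @param frame An `rf_frame` (full-array or subsampled).
#' @param geometry The array geometry the frame's element indices refer to.
#' @param grid A [volume_image()] (or [volume_template()]) defining the
#'   reconstruction grid; its voxel values are ignored.
#' @param envelope If `TRUE`, per-channel envelope detection (magnitude of
#'   the analytic signal) is applied before back-projection.
#' @return A [volume_image()] on the template grid.
#' @export
das_reconstruct <- function(frame, geometry, grid, envelope = FALSE) {
  assert_that(inherits(frame, "rf_frame"), "frame must be an rf_frame")
  assert_that(inherits(grid, "volume_image"), "grid must be a volume_image")
  epos <- geometry$element_positions[frame$element_indices, , drop = FALSE]
  samples <- frame$samples
  if (envelope) samples <- t(apply(samples, 1, analytic_envelope))
  res <- .das_core(samples, epos, voxel_positions(grid),
                   frame$speed_of_sound, frame$sampling_rate / 1e6,
                   frame$t0 * 1e6)
  if (res$n_outside > 0) {
    warning(sprintf(
      "%d voxel-channel delays fell outside the recorded time window",
      res$n_outside), call. = FALSE)
  }
  volume_image(array(res$values, dim(grid$voxels)),
               spacing = grid$spacing, origin = grid$origin)
}

# Magnitude of the analytic signal via the frequency-domain Hilbert method.
analytic_envelope <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(fft(x) * h, inverse = TRUE) / n)
}
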