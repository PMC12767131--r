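#' Simulate photoacoustic RF channel data
#'
#' Forward-simulates per-element time series for a phantom viewed by a
#' hemispherical array. Each absorbing voxel emits a band-limited bipolar
#' wavelet (Gaussian-modulated sinusoid at the transducer centre frequency,
#' envelope width set by the fractional bandwidth), delayed by the one-way
#' time of flight and scaled by `1/distance`; contributions superpose
#' linearly. The model deliberately omits directivity, attenuation and
#' acoustic heterogeneity: it is the simplest physics that reproduces the
#' streak/blur artifact phenomenology of sparse and cluster sampling.
#'
#' @param phantom A [generate_vascular_phantom()] result (or any `phantom`).
#' @param geometry An [build_hemisphere_geometry()] result.
#' @param sampling_rate DAQ sampling rate in Hz (default 40 MHz).
#' @param center_freq Transducer centre frequency in Hz (default 2.02 MHz).
#' @param fractional_bandwidth FWHM bandwidth / centre frequency (default 0.54).
#' @param speed_of_sound Speed of sound in mm/us (default 1.5).
#' @param centre World centre (mm) at which the phantom grid is placed.
#' @param source_threshold Voxels with absorption above this emit; lower
#'   values are treated as acoustically silent to bound cost.
#' @param max_sources Optional cap; if exceeded the strongest sources are
#'   kept (deterministic).
#' @return An object of class `rf_frame`: `samples` (channels x time),
#'   `sampling_rate` (Hz), `speed_of_sound` (mm/us), `t0` (s) and
#'   `element_indices` (1-based indices into the geometry).
#' @export
simulate_pa_rf <- function(phantom, geometry,
                           sampling_rate = 40e6, center_freq = 2.02e6,
                           fractional_bandwidth = 0.54, speed_of_sound = 1.5,
                           centre = c(0, 0, 0), source_threshold = 0.01,
                           max_sources = NULL) {
  assert_that(inherits(phantom, "phantom"), "phantom must be a phantom")
  assert_that(inherits(geometry, "array_geometry"),
              "geometry must be an array_geometry")
  assert_that(sampling_rate > 2 * center_freq * (1 + fractional_bandwidth),
              "sampling_rate undersamples the transducer passband")
  assert_that(speed_of_sound > 0, "speed_of_sound must be positive")

  d <- dim(phantom$absorption_map)
  spacing <- rep(phantom$voxel_spacing, length.out = 3)
  extent <- d * spacing
  sel <- which(phantom$absorption_map > source_threshold)
  if (!is.null(max_sources) && length(sel) > max_sources) {
    ord <- order(phantom$absorption_map[sel], decreasing = TRUE)
    sel <- sel[ord[seq_len(max_sources)]]
  }
  fs <- sampling_rate / 1e6        # MHz; times below in us
  f0 <- center_freq / 1e6
  max_d <- geometry$radius + sqrt(sum(centre^2)) + sqrt(sum(extent^2)) / 2
  sigma_t <- 1 / (2 * pi * (fractional_bandwidth * f0) / 2.35482004503)
  nt <- as.integer(ceiling((max_d / speed_of_sound + 5 * sigma_t) * fs) + 2L)

  if (length(sel) == 0) {
    samples <- matrix(0, geometry$n_elements, nt)
  } else {
    idx <- arrayInd(sel, d)
    src_pos <- sweep(sweep(idx - 0.5, 2, spacing, "*"), 2, extent / 2) +
      matrix(centre, length(sel), 3, byrow = TRUE)
    samples <- .rf_scatter(geometry$element_positions, src_pos,
                           phantom$absorption_map[sel],
                           fs, f0, fractional_bandwidth, speed_of_sound,
                           0, nt)
  }
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 speed_of_sound = speed_of_sound, t0 = 0,
                 element_indices = seq_len(geometry$n_elements)),
            class = "rf_frame")
}

#' @exportS3Method base::print
print.rf_frame <- function(x, ...) {
  cat(sprintf("<rf_frame> %d channels x %d samples @ %.3g MHz, sos %.3g mm/us\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate / 1e6,
              x$speed_of_sound))
  invisible(x)
}

#' Retain a subset of array elements
#'
#' Applies a [subsample_scheme()] to a full-array RF frame: sparse mode keeps
#' elements `stride*i + 1` (i = 0..count-1), cluster mode keeps the block
#' `start..start+count-1`. Channel order follows ascending element index.
#'
#' @param frame An `rf_frame` containing the requested elements.
#' @param geometry The array geometry the frame was recorded with.
#' @param scheme A [subsample_scheme()].
#' @return An `rf_frame` with the retained channels.
#' @export
select_elements <- function(frame, geometry, scheme) {
  assert_that(inherits(frame, "rf_frame"), "frame must be an rf_frame")
  assert_that(inherits(scheme, "subsample_scheme"),
              "scheme must be a subsample_scheme")
  idx <- scheme_indices(scheme, geometry$n_elements)
  pos <- match(idx, frame$element_indices)
  assert_that(!anyNA(pos), "frame does not contain all requested elements")
  out <- frame
  out$samples <- frame$samples[pos, , drop = FALSE]
  out$element_indices <- idx
  out
}
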