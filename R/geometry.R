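#' Hemispherical detector array geometry
#'
#' Places `n_elements` point detectors on a hemisphere of the given radius
#' (pole up, `z >= 0`) using a Fermat-spiral ordering that runs from the pole
#' outward. The ordering is chosen so that both subsampling schemes used in
#' hemispherical-array PACT behave as intended with a single element
#' numbering: a contiguous index prefix `1..k` is a spatially compact cap
#' around the pole (small aperture, the "cluster" regime), while a stride-4
#' index subset covers the whole aperture quasi-uniformly (the "sparse"
#' regime).
#'
#' @param n_elements Number of detector elements (the full array has 1024).
#' @param radius Hemisphere radius in mm.
#' @param ordering Element ordering; only `"spiral"` is implemented.
#' @return An object of class `array_geometry` with fields
#'   `element_positions` (n x 3 matrix, mm), `ordering` (permutation of
#'   `1..n`), `radius` and `n_elements`. Element indices are 1-based.
#' @export
build_hemisphere_geometry <- function(n_elements, radius, ordering = "spiral") {
  assert_that(is.numeric(n_elements) && n_elements >= 1,
              "n_elements must be a positive count")
  assert_that(is.numeric(radius) && radius > 0, "radius must be positive")
  ordering <- match.arg(ordering, "spiral")
  n <- as.integer(n_elements)
  i <- seq_len(n)
  # polar angle: pole (theta = 0) outward to just short of the equator
  cos_theta <- 1 - (i - 0.5) / n
  sin_theta <- sqrt(pmax(0, 1 - cos_theta^2))
  golden <- pi * (3 - sqrt(5))
  phi <- (i - 1) * golden
  pos <- radius * cbind(sin_theta * cos(phi), sin_theta * sin(phi), cos_theta)
  colnames(pos) <- c("x", "y", "z")
  structure(list(element_positions = pos, ordering = i,
                 radius = radius, n_elements = n),
            class = "array_geometry")
}

#' @exportS3Method base::print
print.array_geometry <- function(x, ...) {
  cat(sprintf("<array_geometry> %d elements on hemisphere, radius %.3g mm\n",
              x$n_elements, x$radius))
  cat(sprintf("  polar angle span: %.1f..%.1f deg\n",
              min(polar_angles(x)) * 180 / pi, max(polar_angles(x)) * 180 / pi))
  invisible(x)
}

# Polar angle (rad, 0 at the pole) of each element, optionally of a subset.
polar_angles <- function(geometry, idx = NULL) {
  p <- geometry$element_positions
  if (!is.null(idx)) p <- p[idx, , drop = FALSE]
  acos(pmin(1, pmax(-1, p[, 3] / geometry$radius)))
}

#' Element subsampling scheme
#'
#' Defines which elements of the full array are retained. `"sparse"` keeps
#' elements `stride*i + 1` for `i = 0..count-1` (every 4th element by
#' default, preserving the aperture but increasing angular sparsity);
#' `"cluster"` keeps the contiguous block `start..start+count-1` (a compact
#' cap, shrinking the aperture).
#'
#' @param mode `"sparse"` or `"cluster"`.
#' @param count Number of retained elements.
#' @param stride Index stride for sparse mode (default 4).
#' @param start First index for cluster mode (default 1).
#' @return An object of class `subsample_scheme`.
#' @export
subsample_scheme <- function(mode = c("sparse", "cluster"), count,
                             stride = 4L, start = 1L) {
  mode <- match.arg(mode)
  assert_that(is.numeric(count) && count >= 1, "count must be a positive count")
  assert_that(stride >= 1 && start >= 1, "stride and start must be >= 1")
  structure(list(mode = mode, count = as.integer(count),
                 stride = as.integer(stride), start = as.integer(start)),
            class = "subsample_scheme")
}

# Retained 1-based element indices for a scheme on an n-element array.
scheme_indices <- function(scheme, n_elements) {
  idx <- if (scheme$mode == "sparse") {
    scheme$stride * (seq_len(scheme$count) - 1L) + 1L
  } else {
    seq.int(scheme$start, length.out = scheme$count)
  }
  assert_that(max(idx) <= n_elements,
              sprintf("scheme requires element %d but array has %d",
                      max(idx), n_elements))
  assert_that(!anyDuplicated(idx), "scheme indices must be unique")
  idx
}

#' @exportS3Method base::print
print.subsample_scheme <- function(x, ...) {
  cat(sprintf("<subsample_scheme> %s, %d elements (%s = %d)\n", x$mode,
              x$count, if (x$mode == "sparse") "stride" else "start",
              if (x$mode == "sparse") x$stride else x$start))
  invisible(x)
}
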