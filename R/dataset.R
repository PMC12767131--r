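#' Simulator configuration
#'
#' Bundles the geometry, physics and phantom settings used by
#' [make_paired_dataset()]. Defaults follow the hemispherical-array system
#' the model targets: 1024 elements, 2.02 MHz centre frequency with 54%
#' fractional bandwidth, a 12.8 mm cubic field of view on a 128-cube grid.
#' Quantities the system description does not pin down (hemisphere radius,
#' speed of sound, sampling rate) are physically typical defaults and are
#' configurable here.
#'
#' @param grid_shape Reconstruction grid (voxels per axis).
#' @param fov_mm Field-of-view side length, mm.
#' @param fov_centre World centre of the field of view, mm. The array's
#'   acoustic centre is the origin; offsetting the FOV emulates imaging away
#'   from the sweet spot (as in stitched whole-body scans), which
#'   strengthens the characteristic subsampling artifacts.
#' @param n_elements,radius_mm Array geometry.
#' @param n_branches Vessels per phantom.
#' @param sampling_rate,center_freq Hz.
#' @param fractional_bandwidth FWHM bandwidth over centre frequency.
#' @param speed_of_sound mm/us.
#' @param source_threshold,max_sources Emission bookkeeping, see
#'   [simulate_pa_rf()].
#' @return A named list of class `pact_sim_config`.
#' @export
pact_sim_config <- function(grid_shape = c(128, 128, 128), fov_mm = 12.8,
                            fov_centre = c(0, 0, 0),
                            n_elements = 1024, radius_mm = 60,
                            n_branches = 6,
                            sampling_rate = 40e6, center_freq = 2.02e6,
                            fractional_bandwidth = 0.54,
                            speed_of_sound = 1.5,
                            source_threshold = 0.01, max_sources = NULL) {
  structure(as.list(environment()), class = "pact_sim_config")
}

#' Paired full/subsampled reconstructions
#'
#' Generates `n_pairs` phantoms, simulates full-array RF data once per
#' phantom, and reconstructs each frame twice on the same grid: once from
#' all elements ("full") and once from the elements retained by `scheme`
#' ("degraded"). Both members of a pair are normalised jointly to `[0, 1]`
#' (one min/max per pair, so the pair shares a single intensity scale).
#' Output is bit-reproducible for a fixed seed.
#'
#' @param n_pairs Number of volume pairs.
#' @param scheme A [subsample_scheme()]; e.g. sparse-256 or cluster-128.
#' @param config A [pact_sim_config()].
#' @param seed Integer seed; pair `i` uses `seed + i - 1` for its phantom.
#' @return An object of class `paired_dataset`: a list with `pairs` (each a
#'   list of `full` and `degraded` [volume_image()]s plus the phantom seed),
#'   the `scheme`, `config` and `seed`.
#' @export
make_paired_dataset <- function(n_pairs, scheme, config = pact_sim_config(),
                                seed = 1) {
  assert_that(n_pairs >= 1, "n_pairs must be >= 1")
  assert_that(inherits(scheme, "subsample_scheme"),
              "scheme must be a subsample_scheme")
  geom <- build_hemisphere_geometry(config$n_elements, config$radius_mm)
  centre <- config$fov_centre %||% c(0, 0, 0)
  grid <- volume_template(config$grid_shape, fov_mm = config$fov_mm,
                          centre = centre)
  spacing <- config$fov_mm / config$grid_shape
  pairs <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    s <- seed + i - 1L
    ph <- generate_vascular_phantom(config$grid_shape, spacing,
                                    n_branches = config$n_branches, seed = s)
    frame <- simulate_pa_rf(ph, geom,
                            sampling_rate = config$sampling_rate,
                            center_freq = config$center_freq,
                            fractional_bandwidth = config$fractional_bandwidth,
                            speed_of_sound = config$speed_of_sound,
                            centre = centre,
                            source_threshold = config$source_threshold,
                            max_sources = config$max_sources)
    full <- das_reconstruct(frame, geom, grid)
    degr <- das_reconstruct(select_elements(frame, geom, scheme), geom, grid)
    nrm <- normalize_pair(full$voxels, degr$voxels)
    full$voxels <- nrm[[1]]
    degr$voxels <- nrm[[2]]
    pairs[[i]] <- list(full = full, degraded = degr, seed = s)
  }
  structure(list(pairs = pairs, scheme = scheme, config = config,
                 seed = as.integer(seed)),
            class = "paired_dataset")
}

# Joint min-max normalisation of two arrays to [0, 1] with a shared scale.
normalize_pair <- function(a, b) {
  mn <- min(min(a), min(b))
  mx <- max(max(a), max(b))
  if (mx - mn < 1e-12) return(list(a * 0, b * 0))
  list((a - mn) / (mx - mn), (b - mn) / (mx - mn))
}

#' @export
length.paired_dataset <- function(x) length(x$pairs)

#' @exportS3Method base::print
print.paired_dataset <- function(x, ...) {
  d <- dim(x$pairs[[1]]$full$voxels)
  cat(sprintf("<paired_dataset> %d pairs, %d x %d x %d voxels, scheme %s-%d\n",
              length(x$pairs), d[1], d[2], d[3],
              x$scheme$mode, x$scheme$count))
  invisible(x)
}
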