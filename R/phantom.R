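#' Synthetic vascular phantom
#'
#' Generates a 3D optical-absorption map containing smooth branching tubes
#' on a dark background, standing in for the vascular anatomy imaged by
#' whole-body PACT. Each "vessel" is a persistent random walk rasterised as
#' a Gaussian-profile tube whose radius tapers along its length; each parent
#' walk forks one child branch near its midpoint. Values are clamped to
#' `[0, 1]` and the map is bit-reproducible for a fixed seed.
#'
#' @param grid_shape Integer vector of length 3, voxels per axis.
#' @param voxel_spacing Voxel spacing in mm (scalar or length 3).
#' @param n_branches Number of parent vessels; 0 gives a background-only map.
#' @param seed Integer RNG seed.
#' @param background Background absorption level (default 0).
#' @return An object of class `phantom` with fields `absorption_map`
#'   (3D array in `[0, 1]`), `voxel_spacing` and `seed`.
#' @export
generate_vascular_phantom <- function(grid_shape, voxel_spacing = 0.2,
                                      n_branches = 6, seed = 1,
                                      background = 0) {
  grid_shape <- as.integer(grid_shape)
  assert_that(length(grid_shape) == 3 && all(grid_shape >= 1),
              "grid_shape must be 3 positive counts")
  assert_that(all(voxel_spacing > 0) && length(voxel_spacing) %in% c(1, 3),
              "voxel_spacing must be positive (length 1 or 3)")
  assert_that(n_branches >= 0, "n_branches must be >= 0")
  vol <- array(background, grid_shape)
  if (n_branches > 0) {
    vol <- with_seed(seed, {
      for (b in seq_len(n_branches)) {
        start <- runif(3, 0.2, 0.8) * grid_shape
        dir <- rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        len <- round(runif(1, 0.4, 0.9) * min(grid_shape))
        radius <- runif(1, 1.0, 2.2)
        amp <- runif(1, 0.6, 1.0)
        pts <- walk_centerline(start, dir, len, grid_shape)
        vol <- paint_tube(vol, pts, radius, amp, taper = TRUE)
        # one child branch forking near the parent's midpoint
        mid <- pts[max(1L, nrow(pts) %/% 2L), ]
        cdir <- rnorm(3); cdir <- cdir / sqrt(sum(cdir^2))
        cpts <- walk_centerline(mid, cdir, max(4L, len %/% 2L), grid_shape)
        vol <- paint_tube(vol, cpts, radius * 0.7, amp * 0.9, taper = TRUE)
      }
      vol
    })
  }
  vol <- pmin(pmax(vol, 0), 1)
  structure(list(absorption_map = vol, voxel_spacing = voxel_spacing,
                 seed = as.integer(seed)),
            class = "phantom")
}

# Persistent random walk in voxel coordinates, step 1 voxel, reflected at
# the grid boundary. Returns an n x 3 matrix of centreline points.
walk_centerline <- function(start, dir, len, grid_shape) {
  pts <- matrix(0, len, 3)
  p <- start
  d <- dir
  for (k in seq_len(len)) {
    d <- d + rnorm(3, sd = 0.25)
    d <- d / sqrt(sum(d^2))
    p <- p + d
    # reflect at boundaries (leave a 2-voxel margin)
    for (ax in 1:3) {
      if (p[ax] < 2) { p[ax] <- 4 - p[ax]; d[ax] <- -d[ax] }
      if (p[ax] > grid_shape[ax] - 1) {
        p[ax] <- 2 * (grid_shape[ax] - 1) - p[ax]; d[ax] <- -d[ax]
      }
    }
    pts[k, ] <- p
  }
  pts
}

# Add a Gaussian-profile tube along a centreline; radius optionally tapers
# to 60% at the tip. Accumulates with saturation handled by the caller.
paint_tube <- function(vol, pts, radius, amp, taper = FALSE) {
  d <- dim(vol)
  n <- nrow(pts)
  for (k in seq_len(n)) {
    r <- if (taper) radius * (1 - 0.4 * (k - 1) / max(1, n - 1)) else radius
    hw <- ceiling(2.5 * r)
    c0 <- round(pts[k, ])
    i <- max(1, c0[1] - hw):min(d[1], c0[1] + hw)
    j <- max(1, c0[2] - hw):min(d[2], c0[2] + hw)
    l <- max(1, c0[3] - hw):min(d[3], c0[3] + hw)
    if (!length(i) || !length(j) || !length(l)) next
    di2 <- (i - pts[k, 1])^2
    dj2 <- (j - pts[k, 2])^2
    dl2 <- (l - pts[k, 3])^2
    blob <- amp * exp(-(outer(outer(di2, dj2, "+"), dl2, "+")) / (2 * r^2))
    sub <- vol[i, j, l, drop = FALSE]
    vol[i, j, l] <- pmax(sub, array(blob, dim(sub)))
  }
  vol
}

#' @exportS3Method base::print
print.phantom <- function(x, ...) {
  d <- dim(x$absorption_map)
  cat(sprintf(
    "<phantom> %d x %d x %d voxels @ %.3g mm, %.1f%% absorbing, seed %d\n",
    d[1], d[2], d[3], x$voxel_spacing,
    100 * mean(x$absorption_map > 0.01), x$seed))
  invisible(x)
}
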