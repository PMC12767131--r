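# Shared builders for the test suite. Everything is generated in code;
# sizes are kept small so the default run stays fast.

tiny_geom <- function(n = 1024, radius = 60) {
  build_hemisphere_geometry(n, radius)
}

# A phantom containing a single unit point absorber at the given voxel.
point_phantom <- function(shape, pos, spacing) {
  a <- array(0, shape)
  a[pos[1], pos[2], pos[3]] <- 1
  structure(list(absorption_map = a, voxel_spacing = spacing, seed = 1L),
            class = "phantom")
}

rand_slice <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(runif(n * n), n)
}

# Small network configuration used across network/training tests.
tiny_net_config <- function(...) {
  network_config(base_channels = 4, n_scales = 2, ssm_state_size = 2,
                 time_embed_dim = 8, seed = 3, ...)
}

# Degradation schedule with an alpha of exactly 1/2 at step 2 (T = 3 linear
# schedules never hit 0.5 exactly); used for hand-computed forward checks.
half_alpha_schedule <- function() {
  structure(list(T = 3L, alphas = c(0.999, 0.5, 0)),
            class = "diffusion_schedule")
}

# Flatten a parameter tree to a named list of leaves (for gradient checks).
flatten_tree <- function(tr, prefix = "") {
  if (is.list(tr)) {
    nm <- names(tr)
    if (is.null(nm)) nm <- seq_along(tr)
    unlist(lapply(seq_along(tr), function(i) {
      flatten_tree(tr[[i]], paste0(prefix, ".", nm[i]))
    }), recursive = FALSE)
  } else {
    stats::setNames(list(tr), prefix)
  }
}

# Return a copy of `net` with one flattened parameter entry perturbed.
perturb_param <- function(net, name, k, eps) {
  path <- strsplit(sub("^\\.", "", name), "\\.")[[1]]
  ref <- "net$params"
  for (s in path) ref <- paste0(ref, "[['", s, "']]")
  val <- eval(parse(text = ref))
  val[k] <- val[k] + eps
  eval(parse(text = paste0(ref, " <- val")))
  net
}

expect_rel_equal <- function(actual, expected, tol = 1e-6) {
  denom <- max(abs(expected), 1e-12)
  expect_lt(max(abs(actual - expected)) / denom, tol)
}
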