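#' Restoration network configuration
#'
#' Describes the encoder-decoder restoration network. The U-shape has
#' `n_scales` resolution levels with channel doubling; efficient hybrid
#' Mamba (EHM) blocks sit in the encoder stages and the bottleneck, while
#' the decoder uses plain convolution blocks. Within an EHM block, key and
#' value maps are spatially reduced by `kv_reduction` per axis (strided
#' average pooling) and refined by a selective state-space scan with
#' `ssm_state_size` states per channel before entering scaled-dot-product
#' attention; the attention scale is `C^(1/3)` by default (`sqrt(C)`
#' selectable).
#'
#' @param base_channels Channels at the finest scale.
#' @param n_scales Number of resolution levels (>= 1).
#' @param eca_kernel Kernel size of the channel-attention 1D convolution
#'   (odd).
#' @param kv_reduction Spatial reduction ratio `r` for keys/values (>= 1).
#' @param ssm_state_size State dimension `N` of the selective scan (>= 1).
#' @param attention_scale_mode `"cbrt_C"` or `"sqrt_C"`.
#' @param time_embed_dim Dimension of the sinusoidal time embedding.
#' @param ssm_bypass If `TRUE` the state-space refiner is skipped (the block
#'   degenerates to reduced-KV self-attention); used for equivalence checks.
#' @param seed Seed for weight initialisation.
#' @return A list of class `network_config`.
#' @export
network_config <- function(base_channels = 16, n_scales = 3, eca_kernel = 3,
                           kv_reduction = 2, ssm_state_size = 8,
                           attention_scale_mode = c("cbrt_C", "sqrt_C"),
                           time_embed_dim = 4 * base_channels,
                           ssm_bypass = FALSE, seed = 1) {
  attention_scale_mode <- match.arg(attention_scale_mode)
  assert_that(eca_kernel %% 2 == 1, "eca_kernel must be odd")
  assert_that(kv_reduction >= 1, "kv_reduction must be >= 1")
  assert_that(ssm_state_size >= 1, "ssm_state_size must be >= 1")
  assert_that(n_scales >= 1, "n_scales must be >= 1")
  assert_that(time_embed_dim %% 2 == 0, "time_embed_dim must be even")
  structure(as.list(environment()), class = "network_config")
}

#' Build a restoration network
#'
#' Initialises all weights (seeded, reproducible) for the configuration.
#' The output head is zero-initialised so the untrained network is the
#' identity on the centre slice (the prediction is centre slice + learned
#' residual).
#'
#' @param config A [network_config()].
#' @return An object of class `hd_network` with `params` and `config`.
#' @export
hd_network <- function(config = network_config()) {
  assert_that(inherits(config, "network_config"),
              "config must be a network_config")
  params <- with_seed(config$seed, init_params(config))
  structure(list(params = params, config = config), class = "hd_network")
}

#' @exportS3Method base::print
print.hd_network <- function(x, ...) {
  n <- sum(unlist(tree_map(x$params, length)))
  cat(sprintf(
    "<hd_network> base %d, %d scales, r=%d, N=%d, %s parameters\n",
    x$config$base_channels, x$config$n_scales, x$config$kv_reduction,
    x$config$ssm_state_size, format(n, big.mark = ",")))
  invisible(x)
}

# ---- parameter initialisation ----------------------------------------------

rmat <- function(nr, nc, sd) matrix(rnorm(nr * nc, sd = sd), nr, nc)

init_conv <- function(k, cin, cout, zero = FALSE) {
  sd <- sqrt(2 / (k * k * cin))
  list(w = if (zero) matrix(0, k * k * cin, cout)
           else rmat(k * k * cin, cout, sd),
       b = numeric(cout))
}

init_mamba <- function(C, N) {
  list(w_delta = rmat(C, C, 0.05),
       b_delta = rep(log(exp(0.05) - 1), C),    # softplus^-1(0.05)
       w_b = rmat(C, N, 1 / sqrt(C)),
       w_c = rmat(C, N, 1 / sqrt(C)),
       a_log = matrix(rep(log(seq_len(N)), each = C), C, N),
       d_skip = rep(1, C))
}

init_ehm <- function(C, cfg) {
  sd <- 1 / sqrt(C)
  list(eca_w = rnorm(cfg$eca_kernel, sd = 0.1),
       wq = rmat(C, C, sd), bq = numeric(C),
       wk = rmat(C, C, sd), bk = numeric(C),
       wv = rmat(C, C, sd), bv = numeric(C),
       mk = init_mamba(C, cfg$ssm_state_size),
       mv = init_mamba(C, cfg$ssm_state_size))
}

init_params <- function(cfg) {
  E <- cfg$time_embed_dim
  S <- cfg$n_scales
  ch <- cfg$base_channels * 2^(seq_len(S) - 1)
  m_phi <- 16L
  p <- list(
    tmlp = list(w1 = rmat(E, E, 1 / sqrt(E)), b1 = numeric(E),
                w2 = rmat(E, E, 1 / sqrt(E)), b2 = numeric(E)),
    phi = list(w1 = rmat(2, m_phi, 1 / sqrt(2)), b1 = numeric(m_phi),
               # zero-initialised head: modulation starts as identity
               w2 = matrix(0, m_phi, 2 * E), b2 = numeric(2 * E)),
    stem = init_conv(3, 3, ch[1]),
    enc = vector("list", S),
    dec = if (S > 1) vector("list", S - 1) else list(),
    head = init_conv(3, ch[1], 1, zero = TRUE)
  )
  for (s in seq_len(S)) {
    blk <- list(conv_a = init_conv(3, ch[s], ch[s]),
                time = list(w = rmat(ch[s], E, 1 / sqrt(E)),
                            b = numeric(ch[s])),
                conv_b = init_conv(3, ch[s], ch[s]),
                ehm = init_ehm(ch[s], cfg))
    if (s > 1) blk$down <- init_conv(3, ch[s - 1], ch[s])
    p$enc[[s]] <- blk
  }
  if (S > 1) {
    for (s in seq_len(S - 1)) {
      p$dec[[s]] <- list(
        reduce = init_conv(3, ch[s + 1], ch[s]),
        conv_a = init_conv(3, 2 * ch[s], ch[s]),
        time = list(w = rmat(ch[s], E, 1 / sqrt(E)), b = numeric(ch[s])),
        conv_b = init_conv(3, ch[s], ch[s]))
    }
  }
  p
}

# ---- parameter-tree helpers ------------------------------------------------

tree_map <- function(x, f) {
  if (is.list(x)) lapply(x, tree_map, f = f) else f(x)
}

tree_map2 <- function(a, b, f) {
  if (is.list(a)) Map(tree_map2, a, b, MoreArgs = list(f = f)) else f(a, b)
}

tree_zeros <- function(x) tree_map(x, function(v) v * 0)

tree_add <- function(a, b) tree_map2(a, b, `+`)

# ---- efficient channel attention (exported op) -----------------------------

#' Efficient channel attention
#'
#' Gates each channel of a feature map by a sigmoid attention value obtained
#' from a zero-padded 1D convolution across the globally-averaged channel
#' descriptors: local cross-channel interaction at negligible cost. With
#' all-zero weights every gate is `sigmoid(0) = 0.5`.
#'
#' @param f Feature map, `(X, Y, C)` array.
#' @param weights 1D kernel of odd length `k`.
#' @return The gated feature map, same shape.
#' @export
eca <- function(f, weights) {
  assert_that(length(weights) %% 2 == 1, "kernel length must be odd")
  assert_that(is.array(f) && length(dim(f)) == 3, "f must be (X, Y, C)")
  eca_fwd(f, weights)$y
}

# ---- EHM block -------------------------------------------------------------

ehm_scale <- function(C, mode) if (mode == "cbrt_C") C^(1 / 3) else sqrt(C)

ehm_fwd <- function(f, p, cfg) {
  d <- dim(f)
  r <- cfg$kv_reduction
  assert_that(d[1] %% r == 0 && d[2] %% r == 0,
              "spatial dims must be divisible by kv_reduction")
  ec <- eca_fwd(f, p$eca_w)
  Fm <- raster_flatten(ec$y)
  Qm <- sweep(Fm %*% p$wq, 2, p$bq, "+")
  Km <- sweep(Fm %*% p$wk, 2, p$bk, "+")
  Vm <- sweep(Fm %*% p$wv, 2, p$bv, "+")
  Khat <- avgpool_fwd(raster_unflatten(Km, d[1], d[2]), r)
  Vhat <- avgpool_fwd(raster_unflatten(Vm, d[1], d[2]), r)
  uK <- raster_flatten(Khat)
  uV <- raster_flatten(Vhat)
  if (cfg$ssm_bypass) {
    mk <- mv <- NULL; yK <- uK; yV <- uV
  } else {
    mk <- mamba_fwd(uK, p$mk); yK <- mk$y
    mv <- mamba_fwd(uV, p$mv); yV <- mv$y
  }
  at <- attention_fwd(Qm, yK, yV, ehm_scale(d[3], cfg$attention_scale_mode))
  y <- f + raster_unflatten(at$y, d[1], d[2])
  list(y = y, d = d, ec = ec, Fm = Fm, mk = mk, mv = mv, at = at)
}

ehm_bwd <- function(cache, p, cfg, dy) {
  d <- cache$d
  r <- cfg$kv_reduction
  g <- list()
  ab <- attention_bwd(cache$at, raster_flatten(dy))
  if (cfg$ssm_bypass) {
    duK <- ab$dk; duV <- ab$dv
    g$mk <- tree_zeros(p$mk); g$mv <- tree_zeros(p$mv)
  } else {
    mbk <- mamba_bwd(cache$mk, p$mk, ab$dk)
    mbv <- mamba_bwd(cache$mv, p$mv, ab$dv)
    duK <- mbk$du; duV <- mbv$du
    g$mk <- list(w_delta = mbk$dw_delta, b_delta = mbk$db_delta,
                 w_b = mbk$dw_b, w_c = mbk$dw_c, a_log = mbk$da_log,
                 d_skip = mbk$dd_skip)
    g$mv <- list(w_delta = mbv$dw_delta, b_delta = mbv$db_delta,
                 w_b = mbv$dw_b, w_c = mbv$dw_c, a_log = mbv$da_log,
                 d_skip = mbv$dd_skip)
  }
  x <- d[1] %/% r; yred <- d[2] %/% r
  dKm <- raster_flatten(avgpool_bwd(raster_unflatten(duK, x, yred), r))
  dVm <- raster_flatten(avgpool_bwd(raster_unflatten(duV, x, yred), r))
  dQm <- ab$dq
  g$wq <- t(cache$Fm) %*% dQm; g$bq <- colSums(dQm)
  g$wk <- t(cache$Fm) %*% dKm; g$bk <- colSums(dKm)
  g$wv <- t(cache$Fm) %*% dVm; g$bv <- colSums(dVm)
  dFm <- dQm %*% t(p$wq) + dKm %*% t(p$wk) + dVm %*% t(p$wv)
  eb <- eca_bwd(cache$ec, raster_unflatten(dFm, d[1], d[2]))
  g$eca_w <- eb$dw
  # residual branch plus channel-attention branch
  list(dx = dy + eb$dx,
       grads = g[c("eca_w", "wq", "bq", "wk", "bk", "wv", "bv", "mk", "mv")])
}

#' Efficient hybrid Mamba block
#'
#' One EHM block applied to a feature map: channel attention, pointwise
#' query/key/value projections, spatial reduction of keys and values by the
#' configured ratio, selective state-space refinement of the reduced
#' sequences, scaled-dot-product attention and a residual connection back
#' onto the input.
#'
#' @param f Feature map, `(X, Y, C)` array with spatial dims divisible by
#'   the reduction ratio.
#' @param cfg A [network_config()].
#' @param params Optional block parameters (as produced internally); if
#'   omitted, parameters are initialised from `cfg$seed` for the channel
#'   count of `f`.
#' @return The output feature map, same shape as `f`.
#' @export
ehm_block <- function(f, cfg, params = NULL) {
  assert_that(is.array(f) && length(dim(f)) == 3, "f must be (X, Y, C)")
  if (is.null(params)) {
    params <- with_seed(cfg$seed, init_ehm(dim(f)[3], cfg))
  }
  ehm_fwd(f, params, cfg)$y
}

# ---- error-modulated module (EMM) ------------------------------------------

phi_fwd <- function(p, x0_hat, xT) {
  flat <- cbind(as.vector(x0_hat), as.vector(xT))
  h <- sweep(flat %*% p$w1, 2, p$b1, "+")
  hs <- silu_fwd(h)
  o <- sweep(hs$y %*% p$w2, 2, p$b2, "+")
  g <- colMeans(o)
  E <- length(g) / 2
  list(beta = g[seq_len(E)], gamma = 1 + g[E + seq_len(E)],
       flat = flat, hs = hs, n = nrow(flat))
}

phi_bwd <- function(cache, p, dbeta, dgamma) {
  dg <- c(dbeta, dgamma)
  do <- matrix(dg / cache$n, cache$n, length(dg), byrow = TRUE)
  dh <- silu_bwd(cache$hs, do %*% t(p$w2))
  list(w1 = t(cache$flat) %*% dh, b1 = colSums(dh),
       w2 = t(cache$hs$y) %*% do, b2 = colSums(do))
}

#' Error-modulated time embedding
#'
#' The second sampling stage feeds the network a re-degraded estimate rather
#' than a true intermediate slice, which misaligns the fixed time embedding.
#' A shallow network computes feature-wise linear modulation factors
#' `(beta, gamma)` from the stage-I estimate and the degraded endpoint, and
#' the embedding is calibrated as `gamma * f + beta`. The shallow network's
#' output layer is zero-initialised, so modulation starts as the identity.
#'
#' @param x0_hat Stage-I estimate of the clean slice (matrix).
#' @param xT Degraded endpoint slice (matrix, same shape).
#' @param f_embed Time-embedding vector to modulate.
#' @param net An [hd_network()] (its shallow modulation network is used).
#' @return List with `f_mod` (modulated embedding), `beta` and `gamma`.
#' @export
emm_modulate <- function(x0_hat, xT, f_embed, net) {
  assert_that(all(dim(x0_hat) == dim(xT)), "slice shapes must match")
  ph <- phi_fwd(net$params$phi, x0_hat, xT)
  assert_that(length(f_embed) == length(ph$beta),
              "embedding dimension mismatch")
  list(f_mod = ph$gamma * f_embed + ph$beta,
       beta = ph$beta, gamma = ph$gamma)
}

# ---- full network forward / backward ---------------------------------------

# Forward pass. x: (H, W, 3) triplet; t: integer step; mod: NULL or
# list(beta, gamma). Returns list(out = H x W matrix, cache).
net_forward <- function(params, cfg, x, t, mod = NULL) {
  S <- cfg$n_scales
  E <- cfg$time_embed_dim
  pe <- sinusoidal_embedding(t, E)
  h1 <- as.numeric(params$tmlp$w1 %*% pe + params$tmlp$b1)
  h1s <- silu_fwd(h1)
  ft <- as.numeric(params$tmlp$w2 %*% h1s$y + params$tmlp$b2)
  femb <- if (is.null(mod)) ft else mod$gamma * ft + mod$beta

  cache <- list(pe = pe, h1s = h1s, ft = ft, mod = mod, x = x,
                enc = vector("list", S), dec = vector("list", max(0, S - 1)))
  sc <- conv_fwd(x, params$stem$w, params$stem$b, 3L)
  st <- silu_fwd(sc$y)
  cache$stem_c <- sc; cache$stem_s <- st
  cur <- st$y
  skips <- vector("list", S)
  for (s in seq_len(S)) {
    p <- params$enc[[s]]
    cc <- list()
    if (s > 1) {
      cc$down_c <- conv_fwd(cur, p$down$w, p$down$b, 3L, stride = 2L)
      cc$down_s <- silu_fwd(cc$down_c$y)
      cur <- cc$down_s$y
    }
    cc$a_c <- conv_fwd(cur, p$conv_a$w, p$conv_a$b, 3L)
    tvec <- as.numeric(p$time$w %*% femb + p$time$b)
    cc$a_s <- silu_fwd(sweep(cc$a_c$y, 3, tvec, "+"))
    cur <- cc$a_s$y
    cc$b_c <- conv_fwd(cur, p$conv_b$w, p$conv_b$b, 3L)
    cc$b_s <- silu_fwd(cc$b_c$y)
    cur <- cc$b_s$y
    cc$ehm <- ehm_fwd(cur, p$ehm, cfg)
    cur <- cc$ehm$y
    cache$enc[[s]] <- cc
    if (s < S) skips[[s]] <- cur
  }
  if (S > 1) {
    for (s in rev(seq_len(S - 1))) {
      p <- params$dec[[s]]
      cc <- list()
      cur <- upsample2_fwd(cur)
      cc$r_c <- conv_fwd(cur, p$reduce$w, p$reduce$b, 3L)
      cc$r_s <- silu_fwd(cc$r_c$y)
      cur <- cc$r_s$y
      cc$ncat <- dim(cur)[3]
      cur <- abind3(cur, skips[[s]])
      cc$a_c <- conv_fwd(cur, p$conv_a$w, p$conv_a$b, 3L)
      tvec <- as.numeric(p$time$w %*% femb + p$time$b)
      cc$a_s <- silu_fwd(sweep(cc$a_c$y, 3, tvec, "+"))
      cur <- cc$a_s$y
      cc$b_c <- conv_fwd(cur, p$conv_b$w, p$conv_b$b, 3L)
      cc$b_s <- silu_fwd(cc$b_c$y)
      cur <- cc$b_s$y
      cache$dec[[s]] <- cc
    }
  }
  cache$head_c <- conv_fwd(cur, params$head$w, params$head$b, 3L)
  out <- cache$head_c$y[, , 1] + x[, , 2]
  cache$femb <- femb
  list(out = out, cache = cache)
}

abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

# Backward pass: dout is the H x W gradient on the network output.
# Returns list(grads = parameter-gradient tree, dx = gradient on the input
# triplet, dbeta/dgamma when a modulation was supplied).
net_backward <- function(params, cfg, cache, dout) {
  S <- cfg$n_scales
  g <- tree_zeros(params)
  dfemb <- numeric(cfg$time_embed_dim)
  dx_center <- dout    # global residual on the centre slice

  hb <- conv_bwd(cache$head_c, params$head$w,
                 array(dout, c(dim(dout), 1)), 3L)
  g$head$w <- hb$dw; g$head$b <- hb$db
  dcur <- hb$dx

  dskips <- vector("list", S)
  if (S > 1) {
    for (s in seq_len(S - 1)) {
      p <- params$dec[[s]]
      cc <- cache$dec[[s]]
      dcur <- silu_bwd(cc$b_s, dcur)
      bb <- conv_bwd(cc$b_c, p$conv_b$w, dcur, 3L)
      g$dec[[s]]$conv_b$w <- bb$dw; g$dec[[s]]$conv_b$b <- bb$db
      dcur <- silu_bwd(cc$a_s, bb$dx)
      dtvec <- colSums(matrix(dcur, prod(dim(dcur)[1:2]), dim(dcur)[3]))
      g$dec[[s]]$time$w <- dtvec %o% cache$femb
      g$dec[[s]]$time$b <- dtvec
      dfemb <- dfemb + as.numeric(t(p$time$w) %*% dtvec)
      ab <- conv_bwd(cc$a_c, p$conv_a$w, dcur, 3L)
      g$dec[[s]]$conv_a$w <- ab$dw; g$dec[[s]]$conv_a$b <- ab$db
      nc <- cc$ncat
      dcat <- ab$dx
      dskips[[s]] <- dcat[, , nc + seq_len(dim(dcat)[3] - nc), drop = FALSE]
      dcur <- silu_bwd(cc$r_s, dcat[, , seq_len(nc), drop = FALSE])
      rb <- conv_bwd(cc$r_c, p$reduce$w, dcur, 3L)
      g$dec[[s]]$reduce$w <- rb$dw; g$dec[[s]]$reduce$b <- rb$db
      dcur <- upsample2_bwd(rb$dx)
      # dcur now feeds the next-coarser decoder stage (or the bottleneck)
    }
  }
  for (s in rev(seq_len(S))) {
    p <- params$enc[[s]]
    cc <- cache$enc[[s]]
    if (s < S) dcur <- dcur + dskips[[s]]
    eb <- ehm_bwd(cc$ehm, p$ehm, cfg, dcur)
    g$enc[[s]]$ehm <- eb$grads
    dcur <- silu_bwd(cc$b_s, eb$dx)
    bb <- conv_bwd(cc$b_c, p$conv_b$w, dcur, 3L)
    g$enc[[s]]$conv_b$w <- bb$dw; g$enc[[s]]$conv_b$b <- bb$db
    dcur <- silu_bwd(cc$a_s, bb$dx)
    dtvec <- colSums(matrix(dcur, prod(dim(dcur)[1:2]), dim(dcur)[3]))
    g$enc[[s]]$time$w <- dtvec %o% cache$femb
    g$enc[[s]]$time$b <- dtvec
    dfemb <- dfemb + as.numeric(t(p$time$w) %*% dtvec)
    ab <- conv_bwd(cc$a_c, p$conv_a$w, dcur, 3L)
    g$enc[[s]]$conv_a$w <- ab$dw; g$enc[[s]]$conv_a$b <- ab$db
    dcur <- ab$dx
    if (s > 1) {
      dcur <- silu_bwd(cc$down_s, dcur)
      db <- conv_bwd(cc$down_c, p$down$w, dcur, 3L, stride = 2L)
      g$enc[[s]]$down$w <- db$dw; g$enc[[s]]$down$b <- db$db
      dcur <- db$dx
    }
  }
  dcur <- silu_bwd(cache$stem_s, dcur)
  sb <- conv_bwd(cache$stem_c, params$stem$w, dcur, 3L)
  g$stem$w <- sb$dw; g$stem$b <- sb$db
  dx <- sb$dx
  dx[, , 2] <- dx[, , 2] + dx_center

  # time-embedding path
  mod <- cache$mod
  out <- list(grads = g, dx = dx)
  if (is.null(mod)) {
    dft <- dfemb
  } else {
    out$dbeta <- dfemb
    out$dgamma <- dfemb * cache$ft
    dft <- dfemb * mod$gamma
  }
  g$tmlp$w2 <- dft %o% cache$h1s$y
  g$tmlp$b2 <- dft
  dh1 <- silu_bwd(cache$h1s, as.numeric(t(params$tmlp$w2) %*% dft))
  g$tmlp$w1 <- dh1 %o% cache$pe
  g$tmlp$b1 <- dh1
  out$grads <- g
  out
}

#' Run the restoration network on a slice triplet
#'
#' Predicts the clean centre slice from three adjacent degraded slices
#' (previous, current, next stacked as channels), conditioned on the
#' diffusion step through a sinusoidal embedding passed through a small
#' MLP and injected additively in every block -- optionally calibrated by an
#' [emm_modulate()] modulation during the second sampling stage. The output
#' is deterministic for fixed weights and input.
#'
#' @param net An [hd_network()].
#' @param triplet `(H, W, 3)` array of adjacent slices; `H` and `W` must be
#'   divisible by `2^(n_scales - 1) * kv_reduction`.
#' @param t Diffusion step (integer >= 1).
#' @param modulation Optional result of [emm_modulate()] (uses its
#'   `beta`/`gamma`).
#' @return The predicted clean slice (`H x W` matrix).
#' @export
restoration_forward <- function(net, triplet, t, modulation = NULL) {
  assert_that(inherits(net, "hd_network"), "net must be an hd_network")
  assert_that(is.array(triplet) && length(dim(triplet)) == 3 &&
              dim(triplet)[3] == 3,
              "triplet must be an (H, W, 3) array")
  div <- 2^(net$config$n_scales - 1) * net$config$kv_reduction
  assert_that(all(dim(triplet)[1:2] %% div == 0),
              sprintf("spatial dims must be divisible by %d", div))
  net_forward(net$params, net$config, triplet, t, mod = modulation)$out
}
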