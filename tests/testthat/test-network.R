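test_that("channel attention gates channels as documented", {
  set.seed(1)
  f <- array(runif(8 * 8 * 5), c(8, 8, 5))
  expect_equal(eca(f, c(0, 0, 0)), 0.5 * f, tolerance = 1e-12)
  expect_equal(dim(eca(f, rnorm(3))), dim(f))
  # k = 1 with positive weight: larger channel means get larger gates
  f2 <- array(0, c(4, 4, 3))
  means <- c(0.2, 0.5, 0.9)
  for (c in 1:3) f2[, , c] <- means[c] + 0.01 * matrix(rnorm(16), 4)
  out <- eca(f2, 2)
  gains <- vapply(1:3, function(c) mean(out[, , c]) / mean(f2[, , c]), 0)
  expect_true(all(diff(gains) > 0))
})

test_that("the EHM block preserves shape and normalises attention rows", {
  cfg <- tiny_net_config()
  set.seed(2)
  f <- array(runif(8 * 8 * 4), c(8, 8, 4))
  out <- ehm_block(f, cfg)
  expect_equal(dim(out), dim(f))
  # softmax rows of the internal attention sum to one
  p <- hdpact:::init_ehm(4, cfg)
  cache <- hdpact:::ehm_fwd(f, p, cfg)
  expect_lt(max(abs(rowSums(cache$at$p) - 1)), 1e-6)
  expect_error(ehm_block(array(0, c(7, 8, 4)), cfg),
               class = "hdpact_invalid_argument")
})

test_that("a degenerate EHM block equals plain self-attention", {
  cfg <- network_config(base_channels = 4, kv_reduction = 1,
                        ssm_bypass = TRUE, time_embed_dim = 8, seed = 5)
  C <- 4
  p <- hdpact:::init_ehm(C, cfg)
  p$eca_w[] <- 0                      # gate = 1/2 everywhere
  p$wq <- p$wk <- p$wv <- diag(C)     # identity projections
  p$bq[] <- p$bk[] <- p$bv[] <- 0
  set.seed(3)
  f <- array(runif(6 * 6 * C), c(6, 6, C))
  out <- hdpact:::ehm_fwd(f, p, cfg)$y

  # direct attention comparator on the same gated map
  fE <- 0.5 * f
  q <- hdpact:::raster_flatten(fE)
  s <- q %*% t(q) / C^(1 / 3)
  e <- exp(s - apply(s, 1, max))
  att <- (e / rowSums(e)) %*% q
  ref <- f + hdpact:::raster_unflatten(att, 6, 6)
  expect_lt(max(abs(out - ref)), 1e-9)
})

test_that("key/value reduction shrinks the attention score map by r^2", {
  cfg <- tiny_net_config()
  f <- array(runif(8 * 8 * 4), c(8, 8, 4))
  p <- hdpact:::init_ehm(4, cfg)
  cache <- hdpact:::ehm_fwd(f, p, cfg)
  n <- 8 * 8
  expect_equal(dim(cache$at$p), c(n, n / cfg$kv_reduction^2))
})

test_that("EHM is deterministic and batch permutation-equivariant", {
  cfg <- tiny_net_config()
  set.seed(4)
  batch <- lapply(1:3, function(i) array(runif(8 * 8 * 4), c(8, 8, 4)))
  p <- hdpact:::with_seed(9, hdpact:::init_ehm(4, cfg))
  run <- function(order) lapply(batch[order], function(f)
    hdpact:::ehm_fwd(f, p, cfg)$y)
  expect_identical(run(1:3), run(1:3))
  expect_identical(run(c(2, 3, 1)), run(1:3)[c(2, 3, 1)])
})

test_that("the selective scan layer gradient matches finite differences", {
  set.seed(6)
  L <- 12; C <- 3; N <- 2
  p <- hdpact:::with_seed(1, hdpact:::init_mamba(C, N))
  u <- matrix(rnorm(L * C), L)
  W <- matrix(rnorm(L * C), L)
  fw <- hdpact:::mamba_fwd(u, p)
  bk <- hdpact:::mamba_bwd(fw, p, W)
  loss <- function(pp, uu) sum(W * hdpact:::mamba_fwd(uu, pp)$y)
  eps <- 1e-6
  for (nm in names(p)) {
    k <- sample(length(p[[nm]]), 1)
    pp <- p; pp[[nm]][k] <- pp[[nm]][k] + eps; up <- loss(pp, u)
    pm <- p; pm[[nm]][k] <- pm[[nm]][k] - eps; dn <- loss(pm, u)
    num <- (up - dn) / (2 * eps)
    ana <- bk[[paste0("d", nm)]][k]
    expect_lt(abs(num - ana) / max(1e-4, abs(num) + abs(ana)), 1e-5)
  }
  k <- sample(length(u), 1)
  up <- loss(p, {uu <- u; uu[k] <- uu[k] + eps; uu})
  dn <- loss(p, {uu <- u; uu[k] <- uu[k] - eps; uu})
  expect_lt(abs((up - dn) / (2 * eps) - bk$du[k]) /
              max(1e-4, abs(bk$du[k])), 1e-5)
})

test_that("the full network gradient matches finite differences", {
  cfg <- tiny_net_config()
  net <- hd_network(cfg)
  set.seed(7)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  mod <- list(beta = rnorm(8, sd = 0.1), gamma = 1 + rnorm(8, sd = 0.1))
  W <- matrix(rnorm(64), 8)
  f <- hdpact:::net_forward(net$params, cfg, x, 2, mod = mod)
  bk <- hdpact:::net_backward(net$params, cfg, f$cache, W)
  gf <- flatten_tree(bk$grads)
  loss <- function(nn) sum(W * hdpact:::net_forward(nn$params, cfg, x, 2,
                                                    mod = mod)$out)
  eps <- 1e-6
  for (nm in sample(names(gf), 25)) {
    k <- sample(length(gf[[nm]]), 1)
    num <- (loss(perturb_param(net, nm, k, eps)) -
            loss(perturb_param(net, nm, k, -eps))) / (2 * eps)
    expect_lt(abs(num - gf[[nm]][k]) / max(1e-4, abs(num) + abs(gf[[nm]][k])),
              1e-4)
  }
})

test_that("the modulation network starts as the identity", {
  net <- hd_network(tiny_net_config())
  x0h <- rand_slice(8, 11); xT <- rand_slice(8, 12)
  f <- rnorm(8)
  m <- emm_modulate(x0h, xT, f, net)
  expect_equal(m$beta, rep(0, 8))
  expect_equal(m$gamma, rep(1, 8))
  expect_equal(m$f_mod, f)
  expect_length(m$beta, 8)
  m2 <- emm_modulate(x0h, xT, f, net)
  expect_identical(m, m2)
})

test_that("restoration_forward honours its contract", {
  net <- hd_network(tiny_net_config())
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  out <- restoration_forward(net, x, 2)
  expect_equal(dim(out), c(8L, 8L))
  expect_identical(out, restoration_forward(net, x, 2))
  expect_error(restoration_forward(net, array(0, c(8, 8, 2)), 1),
               class = "hdpact_invalid_argument")
  # zero-initialised head: untrained output is the centre slice
  expect_equal(out, x[, , 2], tolerance = 1e-12)
})
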