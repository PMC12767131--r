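op8 <- build_gabor_operator(gabor_params(), c(8, 8))
sch2 <- alpha_schedule(2)

test_that("losses vanish for a perfect restorer and sum exactly", {
  x0 <- rand_slice(8, 1); xT <- rand_slice(8, 2)
  ctx <- list(prev = rand_slice(8, 3), nxt = rand_slice(8, 4))
  oracle <- function(triplet, t, modulation) x0
  lb <- compute_losses(x0, xT, ctx, oracle, op8, sch2, 2)
  expect_equal(lb$F_stage_I, 0)
  expect_equal(lb$F_stage_II, 0)
  expect_equal(lb$F_error, 0)

  net <- hd_network(tiny_net_config())
  lb2 <- compute_losses(x0, xT, ctx, net, op8, sch2, 2)
  expect_identical(lb2$L_final,
                   lb2$F_stage_I + lb2$F_stage_II + lb2$F_error)
  expect_true(all(c(lb2$F_stage_I, lb2$F_stage_II, lb2$F_error) >= 0))
  expect_error(compute_losses(x0, xT, ctx, net, op8, sch2, 1),
               class = "hdpact_invalid_argument")
})

test_that("a uniform 0.1 stage-I error gives mean-squared loss 0.01", {
  x0 <- matrix(0.3, 4, 4)
  biased <- function(triplet, t, modulation) x0 + 0.1
  op4 <- build_gabor_operator(gabor_params(), c(4, 4))
  ctx <- list(prev = matrix(0.1, 4, 4), nxt = matrix(0.1, 4, 4))
  lb <- compute_losses(x0, matrix(0.2, 4, 4), ctx, biased, op4, sch2, 2)
  expect_equal(lb$F_stage_I, 0.01, tolerance = 1e-12)
})

test_that("loss gradients are finite at initialization across 100 draws", {
  net <- hd_network(tiny_net_config())
  set.seed(31)
  for (i in 1:100) {
    x0 <- rand_slice(8); xT <- rand_slice(8)
    ctx <- list(prev = rand_slice(8), nxt = rand_slice(8))
    lb <- compute_losses(x0, xT, ctx, net, op8, sch2, 2, with_grads = TRUE)
    expect_true(all(vapply(flatten_tree(lb$grads),
                           function(g) all(is.finite(g)), TRUE)))
  }
})

make_toy_pairs <- function(seed = 77, n_slices = 6) {
  set.seed(seed)
  full <- array(0, c(16, 16, n_slices))
  for (k in seq_len(n_slices)) {
    m <- matrix(0, 16, 16)
    m[4:12, 2 * k] <- 1
    m[8, 3:14] <- 0.7
    full[, , k] <- m
  }
  degraded <- pmin(pmax(full * 0.7 +
    0.08 * array(rnorm(length(full)), dim(full)), 0), 1)
  list(list(full = volume_image(full), degraded = volume_image(degraded)))
}

test_that("training is seed-deterministic and its loss decreases", {
  pairs <- make_toy_pairs()
  net <- hd_network(tiny_net_config())
  cfg <- train_config(batch_size = 1, lr = 2e-3, iterations = 50,
                      input_size = 16, seed = 9)
  r1 <- hd_train(net, pairs, cfg)
  r2 <- hd_train(net, pairs, cfg)
  expect_identical(tail(r1$log$L_final, 1), tail(r2$log$L_final, 1))
  expect_identical(r1$net$params, r2$net$params)
  expect_lt(mean(tail(r1$log$L_final, 10)), mean(head(r1$log$L_final, 10)))
  expect_error(hd_train(net, list(), cfg), class = "hdpact_invalid_argument")
})

test_that("checkpoint save/load/resume reproduces the uninterrupted run", {
  pairs <- make_toy_pairs(5)
  net <- hd_network(tiny_net_config())
  cfg <- train_config(batch_size = 1, lr = 2e-3, iterations = 30,
                      input_size = 16, seed = 4)
  full_run <- hd_train(net, pairs, cfg)

  cfg_half <- cfg; cfg_half$iterations <- 15L
  half <- hd_train(net, pairs, cfg_half)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(half$net, ck, state = half$state)
  loaded <- load_checkpoint(ck)
  expect_equal(loaded$net$params, half$net$params)
  expect_true(file.exists(paste0(ck, ".json")))
  sidecar <- jsonlite::read_json(paste0(ck, ".json"))
  expect_true(nzchar(sidecar$config_hash))

  resumed <- hd_train(loaded$net, pairs, cfg, resume = loaded$state)
  expect_equal(resumed$log$L_final, full_run$log$L_final, tolerance = 1e-12)
  expect_equal(resumed$net$params, full_run$net$params, tolerance = 1e-12)
})

test_that("training on x_T = x_0 pairs drives all losses toward zero", {
  set.seed(12)
  v <- array(runif(16 * 16 * 4), c(16, 16, 4))
  pairs <- list(list(full = volume_image(v), degraded = volume_image(v)))
  net <- hd_network(tiny_net_config())
  cfg <- train_config(batch_size = 1, lr = 2e-3, iterations = 40,
                      input_size = 16, seed = 2)
  r <- hd_train(net, pairs, cfg)
  expect_lt(mean(tail(r$log$L_final, 5)), 1e-4)
})

test_that("transfer fine-tuning starts from the pretrained weights", {
  pairs <- make_toy_pairs(8)
  net <- hd_network(tiny_net_config())
  cfg <- train_config(batch_size = 1, lr = 2e-3, iterations = 10,
                      input_size = 16, seed = 3)
  pre <- hd_train(net, pairs, cfg)
  # zero-iteration budget: parameters must equal the checkpoint exactly
  cfg0 <- cfg; cfg0$iterations <- 1L
  ft <- transfer_finetune(pre$net, pairs, cfg0)
  expect_equal(nrow(ft$log), 1)       # iteration budget honoured exactly
  # initialization contract: after a single Adam step every parameter is
  # within one step size of the pretrained checkpoint
  drift <- max(abs(unlist(flatten_tree(ft$net$params)) -
                   unlist(flatten_tree(pre$net$params))))
  expect_lt(drift, 3 * cfg0$lr)
  # architecture mismatch against an expected configuration is rejected
  expect_error(
    transfer_finetune(pre$net, pairs, cfg0,
                      config = network_config(base_channels = 6,
                                              n_scales = 2,
                                              time_embed_dim = 8)),
    class = "hdpact_invalid_argument")
})
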