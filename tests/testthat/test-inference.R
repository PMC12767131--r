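op16 <- build_gabor_operator(gabor_params(), c(16, 16))
sch2 <- alpha_schedule(2)

test_that("the sampler is deterministic and calls the network exactly twice", {
  net <- hd_network(tiny_net_config())
  set.seed(21)
  trip <- array(runif(16 * 16 * 3), c(16, 16, 3))
  a <- sample_slice(net, trip, op16, sch2)
  b <- sample_slice(net, trip, op16, sch2, return_details = TRUE)
  expect_identical(a, b$restored)
  expect_identical(b$n_network_calls, 2L)
  expect_identical(a, sample_slice(net, trip, op16, sch2))
})

test_that("an oracle restorer makes the two-step chain exact", {
  set.seed(22)
  x0 <- rand_slice(16)
  xT <- rand_slice(16)
  oracle <- function(triplet, t, modulation) x0
  trip <- array(c(rand_slice(16), xT, rand_slice(16)), c(16, 16, 3))
  det <- sample_slice(oracle, trip, op16, sch2, return_details = TRUE)
  expect_equal(det$restored, x0)
  # the corrected intermediate equals the true forward slice x_1
  expect_rel_equal(det$x_tm1, forward_degrade(x0, xT, 1, op16, sch2),
                   tol = 1e-6)
})

test_that("the sampler stays finite on adversarial inputs hitting the guard", {
  # an estimate whose spectrum concentrates where alpha * g approaches 1
  spike <- function(triplet, t, modulation) {
    matrix(1e3, 16, 16)
  }
  trip <- array(runif(16 * 16 * 3), c(16, 16, 3))
  out <- sample_slice(spike, trip, op16, sch2)
  expect_true(all(is.finite(out)))
})

test_that("restore_volume preserves geometry and reports clipping", {
  net <- hd_network(tiny_net_config())
  set.seed(23)
  v <- array(runif(16 * 16 * 5), c(16, 16, 5))
  vol <- volume_image(v, spacing = c(0.2, 0.2, 0.4), origin = c(-1, -1, 0))
  res <- restore_volume(net, vol, op16, sch2)
  expect_identical(dim(res$volume$voxels), dim(v))
  expect_identical(res$volume$spacing, vol$spacing)
  expect_identical(res$volume$origin, vol$origin)
  expect_gte(min(res$volume$voxels), 0)
  expect_lte(max(res$volume$voxels), 1)
  expect_length(res$timings, 5)
  expect_error(restore_volume(net, volume_image(v * 5), op16, sch2),
               class = "hdpact_invalid_argument")
})

test_that("identical slices restore identically away from the edges", {
  net <- hd_network(tiny_net_config())
  sl <- rand_slice(16, 24)
  v <- array(rep(sl, 5), c(16, 16, 5))
  res <- restore_volume(net, volume_image(v), op16, sch2)
  for (z in 2:4) {
    expect_equal(res$volume$voxels[, , z], res$volume$voxels[, , 2],
                 tolerance = 1e-12)
  }
})
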