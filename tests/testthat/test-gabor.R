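test_that("the Gabor function matches its closed form", {
  p <- gabor_params()
  expect_equal(gabor_value(p, 0, 0), 1)
  expect_equal(gabor_value(gabor_params(psi = pi / 2), 0, 0), 0)
  expect_equal(gabor_value(gabor_params(theta = 0, lam = 4, sigma = 10), 2, 0),
               -exp(-0.02), tolerance = 1e-12)
  expect_error(gabor_params(lam = -1), class = "hdpact_invalid_argument")
})

test_that("the operator mask is bounded and the operator is linear", {
  for (mode in c("frequency_mask", "spatial_mask")) {
    op <- build_gabor_operator(gabor_params(), c(16, 16), domain_mode = mode)
    expect_equal(dim(op$mask), c(16L, 16L))
    expect_lte(max(abs(op$mask)), 1)
    x <- rand_slice(16, 1); y <- rand_slice(16, 2)
    lhs <- apply_operator(op, 2 * x - 3 * y)
    rhs <- 2 * apply_operator(op, x) - 3 * apply_operator(op, y)
    expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-9)
  }
  expect_error(build_gabor_operator(gabor_params(), c(1, 4)),
               class = "hdpact_invalid_argument")
})

test_that("the alpha schedule is linear from 0.999 to 0", {
  s2 <- alpha_schedule(2)
  expect_identical(s2$alphas, c(0.999, 0))
  s3 <- alpha_schedule(3)
  expect_equal(s3$alphas, c(0.999, 0.4995, 0))
  for (T in c(2, 5, 17)) {
    expect_true(all(diff(alpha_schedule(T)$alphas) < 0))
  }
  expect_error(alpha_schedule(1), class = "hdpact_invalid_argument")
})

test_that("the forward process hits its endpoint and fixed point exactly", {
  op <- build_gabor_operator(gabor_params(), c(8, 8))
  sch <- alpha_schedule(2)
  x0 <- rand_slice(8, 3); xT <- rand_slice(8, 4)
  expect_identical(forward_degrade(x0, xT, 2, op, sch), xT)  # alpha_T = 0
  for (t in 1:2) {
    expect_equal(forward_degrade(xT, xT, t, op, sch), xT, tolerance = 1e-12)
  }
})

test_that("a uniform half-alpha mix averages clean and endpoint slices", {
  # direct evaluation with an all-pass spatial mask and alpha = 1/2
  op <- build_gabor_operator(gabor_params(), c(4, 4),
                             domain_mode = "spatial_mask")
  op$mask <- matrix(1, 4, 4)
  sch <- half_alpha_schedule()
  xt <- forward_degrade(matrix(1, 4, 4), matrix(0, 4, 4), 2, op, sch)
  expect_equal(xt, matrix(0.5, 4, 4), tolerance = 1e-12)
})

test_that("endpoint estimation inverts the forward process in both domains", {
  sch <- alpha_schedule(4)
  for (mode in c("frequency_mask", "spatial_mask")) {
    op <- build_gabor_operator(gabor_params(), c(16, 16), domain_mode = mode)
    for (t in 1:3) {
      for (rep in 1:5) {
        x0 <- rand_slice(16, 100 + rep); xT <- rand_slice(16, 200 + rep)
        xt <- forward_degrade(x0, xT, t, op, sch)
        xTh <- estimate_endpoint(xt, x0, t, op, sch)
        expect_rel_equal(xTh, xT, tol = 1e-6)
      }
    }
  }
})

test_that("endpoint estimation is guarded and trivial at alpha = 0", {
  op <- build_gabor_operator(gabor_params(), c(8, 8))
  sch <- alpha_schedule(2)
  xt <- rand_slice(8, 5)
  expect_identical(estimate_endpoint(xt, rand_slice(8, 6), 2, op, sch), xt)
  # force a transfer value with alpha * g = 1: divisor clamps, output finite
  ops <- build_gabor_operator(gabor_params(), c(8, 8),
                              domain_mode = "spatial_mask")
  ops$mask[] <- 1 / 0.999
  est <- estimate_endpoint(xt, rand_slice(8, 7), 1, ops, sch)
  expect_true(all(is.finite(est)))
})

test_that("the corrected re-degradation step obeys its algebraic identities", {
  op <- build_gabor_operator(gabor_params(), c(16, 16))
  sch <- alpha_schedule(3)
  x0 <- rand_slice(16, 8); xT <- rand_slice(16, 9)
  for (t in 2:3) {
    xt <- forward_degrade(x0, xT, t, op, sch)
    # with the true x0 and true endpoint, the step lands on x_{t-1}
    xth <- estimate_endpoint(xt, x0, t, op, sch)
    out <- renoise_step(xt, x0, xth, t, op, sch)
    expect_rel_equal(out, forward_degrade(x0, xT, t - 1, op, sch), tol = 1e-6)
    # degenerate algebra: x0_hat = xt_hat makes both forward terms cancel
    z <- rand_slice(16, 10 + t)
    expect_equal(renoise_step(xt, z, z, t, op, sch), xt, tolerance = 1e-9)
  }
  expect_error(renoise_step(x0, x0, x0, 1, op, sch),
               class = "hdpact_invalid_argument")
  # linearity in each slice argument
  a <- rand_slice(16, 20); b <- rand_slice(16, 21); c <- rand_slice(16, 22)
  lhs <- renoise_step(a, 2 * b, c, 2, op, sch)
  rhs <- 2 * renoise_step(a, b, c, 2, op, sch) -
    renoise_step(a, 0 * b, c, 2, op, sch)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})
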