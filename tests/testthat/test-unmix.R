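synth_eps <- function() {
  extinction_table(c(730, 756, 796, 866),
                   eps_hbo = c(400, 470, 770, 1100),
                   eps_hbr = c(1100, 1550, 780, 690))
}

synth_volumes <- function(C_hbo, C_hbr, table) {
  E <- table$epsilon
  lapply(seq_len(nrow(E)), function(k)
    E[k, 1] * C_hbo + E[k, 2] * C_hbr)
}

test_that("noise-free unmixing recovers concentrations exactly", {
  set.seed(1)
  d <- c(6, 6, 6)
  C_hbo <- array(runif(prod(d)), d)
  C_hbr <- array(runif(prod(d)), d)
  tb <- synth_eps()
  vols <- synth_volumes(C_hbo, C_hbr, tb)
  maps <- lsq_unmix(vols, tb, prefilter = FALSE)
  expect_lt(max(abs(maps$C_HbO - C_hbo)) / max(C_hbo), 1e-10)
  expect_lt(max(abs(maps$C_HbR - C_hbr)) / max(C_hbr), 1e-10)

  zero <- lsq_unmix(lapply(1:4, function(i) array(0, d)), tb,
                    prefilter = FALSE)
  expect_true(all(zero$C_HbO == 0) && all(zero$C_HbR == 0))

  expect_error(extinction_table(c(730, 756), c(1, 2), c(2, 4)),
               class = "hdpact_invalid_argument")
  expect_error(lsq_unmix(vols[1:3], tb), class = "hdpact_invalid_argument")
})

test_that("laser-power normalisation and the median prefilter are applied", {
  set.seed(2)
  d <- c(5, 5, 5)
  C_hbo <- array(runif(prod(d)), d)
  C_hbr <- array(runif(prod(d)), d)
  tb <- synth_eps()
  vols <- synth_volumes(C_hbo, C_hbr, tb)
  powers <- c(1.1, 0.9, 1.3, 0.8)
  scaled <- Map(function(v, p) v * p, vols, powers)
  maps <- lsq_unmix(scaled, tb, laser_powers = powers, prefilter = FALSE)
  expect_lt(max(abs(maps$C_HbO - C_hbo)) / max(C_hbo), 1e-10)
  # prefilter: a single hot voxel in a constant volume is removed
  flat <- array(1, d)
  spiky <- flat
  spiky[3, 3, 3] <- 100
  filtered <- hdpact:::median_filter3(spiky)
  expect_equal(filtered, flat)
})

test_that("sO2 recovery tolerates 1% noise with < 5% median error", {
  set.seed(3)
  d <- c(8, 8, 8)
  so2_true <- array(runif(prod(d), 0.3, 0.95), d)
  hbt <- array(runif(prod(d), 0.5, 1), d)
  C_hbo <- so2_true * hbt
  C_hbr <- hbt - C_hbo
  tb <- synth_eps()
  vols <- synth_volumes(C_hbo, C_hbr, tb)
  scale <- max(unlist(lapply(vols, max)))
  noisy <- lapply(vols, function(v) v + array(rnorm(prod(d),
                                                    sd = 0.01 * scale), d))
  maps <- compute_so2_hbt(lsq_unmix(noisy, tb, prefilter = FALSE),
                          hbt_floor = 0)
  rel <- abs(maps$sO2 - so2_true) / so2_true
  expect_lt(median(rel, na.rm = TRUE), 0.05)
})

test_that("sO2 and HbT obey their defining identities and masking", {
  m <- structure(list(C_HbO = array(2, c(2, 2, 2)),
                      C_HbR = array(2, c(2, 2, 2)),
                      clamped = array(FALSE, c(2, 2, 2))),
                 class = "chromophore_maps")
  r <- compute_so2_hbt(m, hbt_floor = 0.1)
  expect_true(all(r$sO2 == 0.5))
  expect_true(all(r$C_HbT == 4))

  m$C_HbR[] <- 0
  r2 <- compute_so2_hbt(m, hbt_floor = 0.1)
  expect_true(all(r2$sO2 == 1))

  m$C_HbO[1, 1, 1] <- 0
  m$C_HbR[1, 1, 1] <- 0
  r3 <- compute_so2_hbt(m, hbt_floor = 0.1)
  expect_true(is.na(r3$sO2[1, 1, 1]))
  expect_false(r3$valid[1, 1, 1])
  # additivity holds exactly wherever valid
  expect_identical(r3$C_HbT, r3$C_HbO + r3$C_HbR)
  expect_true(all(r3$sO2[r3$valid] >= 0 & r3$sO2[r3$valid] <= 1))
})

test_that("the shipped extinction table loads with full rank", {
  tb <- default_extinction_table()
  expect_length(tb$wavelengths, 4)
  expect_equal(qr(tb$epsilon)$rank, 2)
})
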