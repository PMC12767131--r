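test_that("PSNR matches its closed forms", {
  x <- rand_slice(8, 1)
  p <- psnr(x, x)
  expect_true(is.infinite(p))
  expect_true(attr(p, "zero_mse"))
  expect_equal(as.numeric(psnr(x, x + 0.1)), 20, tolerance = 1e-9)
  expect_equal(as.numeric(psnr(x, x + 0.5)), 10 * log10(4), tolerance = 1e-9)
})

test_that("SSIM matches its closed forms and is symmetric", {
  x <- rand_slice(16, 2); y <- rand_slice(16, 3)
  expect_equal(ssim(x, x), 1)
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
  C1 <- 1e-4
  expect_equal(ssim(matrix(0, 8, 8), matrix(1, 8, 8)),
               C1 / (1 + C1), tolerance = 1e-12)
  expect_error(ssim(x, y, C1 = 0), class = "hdpact_invalid_argument")
})

test_that("PSNR and windowed SSIM agree with scikit-image on 50 random pairs", {
  set.seed(9)
  n <- 24
  pairs <- lapply(1:50, function(i)
    list(x = rand_slice(n), y = rand_slice(n)))
  tmp <- tempfile(fileext = ".csv")
  m <- do.call(rbind, lapply(pairs, function(p) c(as.vector(p$x),
                                                  as.vector(p$y))))
  utils::write.table(m, tmp, row.names = FALSE, col.names = FALSE, sep = ",")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, numpy as np",
    "from skimage.metrics import peak_signal_noise_ratio as psnr",
    "from skimage.metrics import structural_similarity as ssim",
    sprintf("n = %d", n),
    sprintf("m = np.loadtxt('%s', delimiter=',')", tmp),
    "for row in m:",
    "    x = row[:n*n].reshape(n, n, order='F')",
    "    y = row[n*n:].reshape(n, n, order='F')",
    "    print(psnr(y, x, data_range=1),",
    "          ssim(x, y, data_range=1, win_size=7,",
    "               gaussian_weights=False))"), script)
  out <- system2("python", script, stdout = TRUE)
  ref <- do.call(rbind, lapply(strsplit(out, " +"), as.numeric))
  for (i in 1:50) {
    expect_equal(as.numeric(psnr(pairs[[i]]$x, pairs[[i]]$y)), ref[i, 1],
                 tolerance = 1e-6)
    expect_equal(ssim(pairs[[i]]$x, pairs[[i]]$y, window = 7), ref[i, 2],
                 tolerance = 1e-6)
  }
})

test_that("metric_report summarises per-slice and overall quality", {
  set.seed(4)
  v <- array(runif(8 * 8 * 4), c(8, 8, 4))
  w <- v + 0.05
  rep <- metric_report(volume_image(w), volume_image(v))
  expect_equal(rep$psnr, 10 * log10(1 / 0.0025), tolerance = 1e-9)
  expect_equal(nrow(rep$per_slice), 4)
  expect_true(all(rep$per_slice$ssim <= 1))
})
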