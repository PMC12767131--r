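#' Gabor filter parameters
#'
#' The degradation operator of the diffusion forward process is a Gabor
#' filter: a Gaussian envelope modulating a sinusoid, acting as an
#' orientation- and frequency-selective linear filter. Defaults are the
#' values used for the PA-matched forward process: orientation `pi/4`,
#' wavelength 3.3, Gaussian sd 10, phase 0, ellipticity 1 (wavelength,
#' sd in pixel or frequency-bin units depending on the operator domain).
#'
#' @param theta Orientation, radians.
#' @param lam Sinusoid wavelength, pixels (> 0).
#' @param sigma Gaussian standard deviation, pixels (> 0).
#' @param psi Phase offset, radians.
#' @param gamma Ellipticity ratio (> 0).
#' @return An object of class `gabor_params`.
#' @export
gabor_params <- function(theta = pi / 4, lam = 3.3, sigma = 10,
                         psi = 0, gamma = 1) {
  assert_that(lam > 0, "lam must be positive")
  assert_that(sigma > 0, "sigma must be positive")
  assert_that(gamma > 0, "gamma must be positive")
  structure(list(theta = theta, lam = lam, sigma = sigma,
                 psi = psi, gamma = gamma),
            class = "gabor_params")
}

#' Evaluate the Gabor function
#'
#' `G(i, j) = exp(-(i'^2 + gamma^2 j'^2) / (2 sigma^2)) * cos(2 pi i'/lam + psi)`
#' with `i' = i cos(theta) + j sin(theta)`, `j' = -i sin(theta) + j cos(theta)`.
#' Vectorised over `i`/`j`.
#'
#' @param params A [gabor_params()].
#' @param i,j Coordinates (same length or broadcastable).
#' @return Numeric values in `[-1, 1]`.
#' @export
gabor_value <- function(params, i, j) {
  ip <- i * cos(params$theta) + j * sin(params$theta)
  jp <- -i * sin(params$theta) + j * cos(params$theta)
  exp(-(ip^2 + params$gamma^2 * jp^2) / (2 * params$sigma^2)) *
    cos(2 * pi * ip / params$lam + params$psi)
}

#' Build the degradation operator
#'
#' Evaluates the Gabor function on a grid centred at the array midpoint and
#' wraps it as a linear operator on same-shaped 2D slices. In
#' `"frequency_mask"` mode (default) the mask multiplies the slice's 2D
#' spectrum pointwise on centred frequency coordinates -- the filter
#' selectively removes spatial-frequency components, and the reverse-process
#' endpoint estimate inverts it by guarded pointwise division. In
#' `"spatial_mask"` mode the mask multiplies pixelwise in image space. Both
#' are linear and self-adjoint (the mask is real).
#'
#' @param params A [gabor_params()].
#' @param shape Length-2 integer vector (rows, cols), at least 2 x 2.
#' @param domain_mode `"frequency_mask"` or `"spatial_mask"`.
#' @param guard_eps Lower bound on `|1 - alpha * g|` in the endpoint
#'   inversion (the inversion is singular where `alpha * g -> 1`).
#' @return An object of class `degradation_operator` with the centred `mask`,
#'   the `domain_mode`, `shape` and `guard_eps`.
#' @export
build_gabor_operator <- function(params, shape,
                                 domain_mode = c("frequency_mask",
                                                 "spatial_mask"),
                                 guard_eps = 1e-3) {
  domain_mode <- match.arg(domain_mode)
  shape <- as.integer(shape)
  assert_that(length(shape) == 2 && all(shape >= 2),
              "shape must be at least 2 x 2")
  ci <- (seq_len(shape[1]) - 1) - floor(shape[1] / 2)
  cj <- (seq_len(shape[2]) - 1) - floor(shape[2] / 2)
  mask <- outer(ci, cj, function(i, j) gabor_value(params, i, j))
  op <- structure(list(mask = mask, domain_mode = domain_mode,
                       shape = shape, params = params,
                       guard_eps = guard_eps),
                  class = "degradation_operator")
  if (domain_mode == "frequency_mask") {
    # Reorder the centred mask to match R's unshifted FFT layout, then
    # average each bin with its conjugate partner (-k mod N). For psi = 0
    # this only touches the partnerless Nyquist row/column of even-sized
    # grids; it makes the operator map real slices to real slices exactly,
    # so the pointwise endpoint inversion is exact rather than approximate.
    m <- ifftshift2(mask)
    fr <- c(1, rev(seq_len(nrow(m))[-1]))
    fc <- c(1, rev(seq_len(ncol(m))[-1]))
    op$mask_fft <- (m + m[fr, fc]) / 2
  }
  op
}

# inverse fftshift: move the centred (0,0) bin back to index [1,1]
ifftshift2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  m[c((floor(h / 2) + 1):h, seq_len(floor(h / 2))),
    c((floor(w / 2) + 1):w, seq_len(floor(w / 2)))]
}

#' Apply a degradation operator to a slice
#'
#' @param op A [build_gabor_operator()] result.
#' @param x 2D numeric matrix matching the operator shape.
#' @return The filtered slice (real matrix).
#' @export
apply_operator <- function(op, x) {
  assert_that(all(dim(x) == op$shape), "slice shape must match operator")
  if (op$domain_mode == "spatial_mask") return(op$mask * x)
  Re(fft(fft(x) * op$mask_fft, inverse = TRUE)) / length(x)
}

#' Linear degradation schedule
#'
#' Weights `alpha_t = 0.999 * (T - t) / (T - 1)` for `t = 1..T`: linear from
#' 0.999 down to exactly 0, strictly decreasing. At `alpha_T = 0` the forward
#' process returns the degraded endpoint unchanged.
#'
#' @param T Number of diffusion steps (>= 2; the deployed model uses 2).
#' @return An object of class `diffusion_schedule` with fields `T`, `alphas`.
#' @export
alpha_schedule <- function(T) {
  assert_that(is.numeric(T) && T >= 2, "T must be >= 2")
  T <- as.integer(T)
  structure(list(T = T, alphas = 0.999 * (T - seq_len(T)) / (T - 1)),
            class = "diffusion_schedule")
}

schedule_alpha <- function(sched, t) {
  assert_that(t >= 1 && t <= sched$T, "t out of schedule range")
  sched$alphas[t]
}

#' Diffusion forward process
#'
#' `D(x0, xT, t) = alpha_t G x0 + (1 - alpha_t G) xT
#'              = xT + alpha_t G (x0 - xT)`:
#' interpolates between the clean slice `x0` and the degraded endpoint `xT`
#' through the Gabor operator `G`. At `alpha_t = 0` (i.e. `t = T`) it returns
#' `xT` bit-exactly; if `x0 == xT` every step returns `xT`.
#'
#' @param x0 Clean slice (matrix).
#' @param xT Degraded endpoint slice (matrix, same shape).
#' @param t Step in `1..T`.
#' @param op A [build_gabor_operator()] result.
#' @param sched An [alpha_schedule()] result.
#' @return The intermediate slice `x_t`.
#' @export
forward_degrade <- function(x0, xT, t, op, sched) {
  assert_that(all(dim(x0) == dim(xT)), "x0 and xT shapes must match")
  a <- schedule_alpha(sched, t)
  if (a == 0) return(xT)
  xT + a * apply_operator(op, x0 - xT)
}

#' Estimate the degraded endpoint from an intermediate slice
#'
#' Inverts the forward combination pointwise in the operator's diagonalising
#' domain: `x_hat_T = (x_t - alpha_t G x0_hat) / (1 - alpha_t G)`, where the
#' division acts on transfer values (frequency bins for the frequency mask,
#' pixels for the spatial mask). Divisors smaller in magnitude than
#' `guard_eps` are clamped to `+/- guard_eps`, so the output is always
#' finite. At `alpha_t = 0` the slice is returned unchanged.
#'
#' @param xt Intermediate slice at step `t`.
#' @param x0_hat Estimate of the clean slice.
#' @param t Step in `1..T`.
#' @inheritParams forward_degrade
#' @return The endpoint estimate `x_hat_T`.
#' @export
estimate_endpoint <- function(xt, x0_hat, t, op, sched) {
  assert_that(all(dim(xt) == dim(x0_hat)), "slice shapes must match")
  a <- schedule_alpha(sched, t)
  if (a == 0) return(xt)
  div_guard <- function(d) {
    s <- ifelse(d >= 0, 1, -1)
    s * pmax(abs(d), op$guard_eps)
  }
  if (op$domain_mode == "spatial_mask") {
    return((xt - a * op$mask * x0_hat) / div_guard(1 - a * op$mask))
  }
  num <- fft(xt) - a * op$mask_fft * fft(x0_hat)
  Re(fft(num / div_guard(1 - a * op$mask_fft), inverse = TRUE)) / length(xt)
}

#' Corrected re-degradation step of the sampler
#'
#' `x_hat_{t-1} = x_t - D(x0_hat, xt_hat, t) + D(x0_hat, xt_hat, t - 1)`:
#' instead of re-running the forward process from the network estimate alone
#' (which accumulates restoration error step by step), the sampler keeps the
#' observed `x_t` and only moves it by the difference between two forward
#' evaluations built from the estimated endpoint `xt_hat`.
#'
#' @param xt Observed slice at step `t`.
#' @param x0_hat Network estimate of the clean slice.
#' @param xt_hat Endpoint estimate from [estimate_endpoint()].
#' @param t Step, must be >= 2 (the forward process is never evaluated at 0).
#' @inheritParams forward_degrade
#' @return The corrected slice at step `t - 1`.
#' @export
renoise_step <- function(xt, x0_hat, xt_hat, t, op, sched) {
  assert_that(t >= 2, "renoise_step requires t >= 2")
  xt - forward_degrade(x0_hat, xt_hat, t, op, sched) +
    forward_degrade(x0_hat, xt_hat, t - 1, op, sched)
}
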