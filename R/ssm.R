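#' Zero-order-hold discretization of a state-space model
#'
#' Converts the continuous linear system `x'(t) = A x(t) + B u(t)`,
#' `y(t) = C x(t)` to the discrete recurrence `x_t = Abar x_{t-1} + Bbar u_t`
#' with step size `delta`, using the zero-order hold:
#' `Abar = exp(delta A)`, `Bbar = (delta A)^{-1} (exp(delta A) - I) delta B`.
#' When `||delta A||` is below `1e-6` the matrix inverse is replaced by the
#' series limit `(I + delta A / 2 + (delta A)^2 / 6 + ...) delta B`, which
#' covers `delta = 0` and singular `A` (where `Bbar -> delta B`).
#'
#' @param A N x N dynamics matrix (a scalar is treated as 1 x 1).
#' @param B N x 1 input matrix (or scalar / length-N vector).
#' @param delta Step size (>= 0).
#' @return List with `Abar` (N x N) and `Bbar` (N x 1).
#' @export
ssm_discretize <- function(A, B, delta) {
  A <- as.matrix(A)
  B <- matrix(B, nrow = nrow(A))
  dA <- delta * A
  Abar <- as.matrix(Matrix::expm(Matrix::Matrix(dA)))
  nrm <- max(abs(dA))
  if (nrm < 1e-6) {
    # (dA)^{-1}(exp(dA) - I) = I + dA/2 + dA^2/6 + ... ; truncation error
    # below machine precision at this norm
    S <- diag(nrow(A)) + dA / 2 + dA %*% dA / 6
    Bbar <- S %*% (delta * B)
  } else {
    Bbar <- solve(dA, (Abar - diag(nrow(A))) %*% (delta * B))
  }
  list(Abar = Abar, Bbar = Bbar)
}

#' Discrete state-space recurrence
#'
#' Runs `x_t = Abar x_{t-1} + Bbar u_t`, `y_t = C x_t` over a scalar input
#' sequence, with `x_0 = 0`.
#'
#' @param params List with `Abar` (N x N), `Bbar` (N x 1), `C` (1 x N, a
#'   vector is accepted).
#' @param u Numeric input sequence of length L.
#' @return Numeric output sequence `y` of length L.
#' @export
ssm_recurrence <- function(params, u) {
  Abar <- as.matrix(params$Abar)
  Bbar <- matrix(params$Bbar, nrow = nrow(Abar))
  Cm <- matrix(params$C, nrow = 1)
  x <- matrix(0, nrow(Abar), 1)
  y <- numeric(length(u))
  for (t in seq_along(u)) {
    x <- Abar %*% x + Bbar * u[t]
    y[t] <- as.numeric(Cm %*% x)
  }
  y
}

#' State-space output as a global causal convolution
#'
#' The same map as [ssm_recurrence()], computed through the impulse-response
#' kernel `Kbar = (C Bbar, C Abar Bbar, ..., C Abar^{L-1} Bbar)`:
#' `y = u * Kbar` (causal convolution).
#'
#' @inheritParams ssm_recurrence
#' @return Numeric output sequence `y` of length L.
#' @export
ssm_convolution <- function(params, u) {
  L <- length(u)
  k <- ssm_kernel(params, L)
  y <- numeric(L)
  for (t in seq_len(L)) {
    y[t] <- sum(k[seq_len(t)] * u[t:1])
  }
  y
}

#' Impulse-response kernel of a discrete state-space model
#'
#' @inheritParams ssm_recurrence
#' @param L Kernel length.
#' @return Numeric vector `(C Bbar, C Abar Bbar, ..., C Abar^{L-1} Bbar)`.
#' @export
ssm_kernel <- function(params, L) {
  Abar <- as.matrix(params$Abar)
  v <- matrix(params$Bbar, nrow = nrow(Abar))
  Cm <- matrix(params$C, nrow = 1)
  k <- numeric(L)
  for (t in seq_len(L)) {
    k[t] <- as.numeric(Cm %*% v)
    v <- Abar %*% v
  }
  k
}
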