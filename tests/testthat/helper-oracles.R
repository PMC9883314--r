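# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Classic fixed-step RK4 integration of dc/dt = c_in*F/V - c*F*kappa/V.
rk4_df <- function(c0, c_in, F, V, kappa, t_end, h = 1e-3) {
  rhs <- function(c) c_in * F / V - c * F * kappa / V
  nstep <- ceiling(t_end / h)
  h <- t_end / nstep
  c <- c0
  for (i in seq_len(nstep)) {
    k1 <- rhs(c)
    k2 <- rhs(c + h / 2 * k1)
    k3 <- rhs(c + h / 2 * k2)
    k4 <- rhs(c + h * k3)
    c <- c + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  c
}

# Dense-arithmetic reference for one EKF predict/update cycle (state x,
# covariance P, transition exponent applied outside).
dense_ekf_update <- function(x, P, z, sigma_w) {
  H <- matrix(c(1, 0, 1), nrow = 1)
  S <- drop(H %*% P %*% t(H)) + sigma_w^2
  K <- P %*% t(H) / S
  zhat <- x[1] + x[3]
  x_post <- x + drop(K) * (z - zhat)
  P_post <- (diag(3) - K %*% H) %*% P
  list(x = x_post, P = P_post, K = drop(K), S = S)
}

# Plain linear Kalman filter on the 2-state (delta signal, offset) system
# with a known decay factor a = exp(-x2); oracle for the EKF's linear limit.
linear_kf <- function(z, a, x0, P0, sigma_v, sigma_w) {
  Fm <- matrix(c(a, 0, 0, 1), 2, 2, byrow = TRUE)
  H <- matrix(c(1, 1), nrow = 1)
  Q <- diag(c(sigma_v^2, 0))
  x <- x0
  P <- P0
  filtered <- numeric(length(z))
  for (k in seq_along(z)) {
    if (k > 1) {
      x <- Fm %*% x
      P <- Fm %*% P %*% t(Fm) + Q
    }
    S <- drop(H %*% P %*% t(H)) + sigma_w^2
    K <- P %*% t(H) / S
    x <- x + K * drop(z[k] - H %*% x)
    P <- (diag(2) - K %*% H) %*% P
    filtered[k] <- sum(x)
  }
  filtered
}

# Two-component Beer-Lambert spectrum generator for chemometrics tests.
make_spectra <- function(n, wn = seq(300, 3100, by = 4), noise = 0,
                         c1 = NULL, c2 = NULL) {
  p1 <- exp(-(wn - 950)^2 / (2 * 15^2))
  p2 <- exp(-(wn - 1000)^2 / (2 * 18^2))
  if (is.null(c1)) c1 <- stats::runif(n, 0, 10)
  if (is.null(c2)) c2 <- stats::runif(n, 0, 5)
  X <- outer(c1, p1) + outer(c2, p2)
  if (noise > 0) X <- X + matrix(stats::rnorm(n * length(wn), 0, noise),
                                 n, length(wn))
  list(X = X, y = c1, c2 = c2, wn = wn, p1 = p1, p2 = p2)
}

# Small DF-only recipe for fast chain tests.
mini_df_recipe <- function(kappa = 1, dv = 8, F = 4.5, V0 = 45) {
  process_recipe(
    name = "mini",
    phases = list(list(kind = "DF", dv = dv)),
    F = F, V0 = V0,
    species = data.frame(name = "citrate", c0 = 50, c_in = 0,
                         kappa = kappa, drho = 0.075),
    protein = list(name = "prot", c0 = 20, extinction = 2, a_prot = 0.26))
}

mini_library <- function() {
  spectral_library(
    components = list(
      protein = data.frame(center = c(1006, 1448, 2942),
                           width = c(8, 12, 20), amplitude = c(6, 4.5, 8)),
      citrate = data.frame(center = c(840, 952, 1412), width = c(9, 9, 10),
                           amplitude = c(1.2, 2.5, 1.8))),
    background_amp = 8)
}
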