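#' Extended Kalman filter state for buffer-exchange monitoring
#'
#' Three-state estimate used to track a scalar signal that relaxes
#' exponentially during diafiltration:
#' * `x1` — delta buffer signal, the distance of the current signal from its
#'   terminal value (signal units; negative for increasing signals),
#' * `x2` — per-step exchange-rate exponent `kappa * F * dt / V`
#'   (dimensionless; the state transition is `x1 <- x1 * exp(-x2)`),
#' * `x3` — terminal signal offset, i.e. the steady-state signal height.
#'
#' The observation model is `z = x1 + x3`.
#'
#' @param x1,x2,x3 State entries (see above).
#' @param P 3x3 state covariance matrix (symmetric positive semi-definite).
#' @return An object of class `ekf_state`.
#' @export
ekf_state <- function(x1, x2, x3, P) {
  stopifnot(is.numeric(x1), is.numeric(x2), is.numeric(x3))
  if (!all(is.finite(c(x1, x2, x3)))) stop("ekf_state: non-finite state entries")
  P <- as.matrix(P)
  if (!all(dim(P) == c(3L, 3L)) || !all(is.finite(P)))
    stop("ekf_state: P must be a finite 3x3 matrix")
  if (max(abs(P - t(P))) > 1e-8 * max(1, max(abs(P))))
    stop("ekf_state: P must be symmetric")
  P <- (P + t(P)) / 2
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(sum(diag(P)), .Machine$double.eps))
    stop("ekf_state: P must be positive semi-definite")
  structure(list(x = c(x1 = unname(x1), x2 = unname(x2), x3 = unname(x3)),
                 P = P), class = "ekf_state")
}

#' @export
print.ekf_state <- function(x, ...) {
  cat("EKF state: x1 =", signif(x$x[1], 5), " x2 =", signif(x$x[2], 5),
      " x3 =", signif(x$x[3], 5), "\n")
  cat("P diag:", signif(diag(x$P), 4), "\n")
  invisible(x)
}

#' Process and sensor noise for the buffer-exchange EKF
#'
#' @param sigma_v Process-noise standard deviation acting on `x1`
#'   (signal units, >= 0). The exchange rate and offset states carry no
#'   process noise.
#' @param sigma_w Sensor-noise standard deviation (signal units, > 0).
#' @return An object of class `ekf_noise`.
#' @export
ekf_noise <- function(sigma_v, sigma_w) {
  if (!is.finite(sigma_v) || sigma_v < 0) stop("ekf_noise: sigma_v must be >= 0")
  if (!is.finite(sigma_w) || sigma_w <= 0) stop("ekf_noise: sigma_w must be > 0")
  structure(list(sigma_v = sigma_v, sigma_w = sigma_w), class = "ekf_noise")
}

# Largest exponent magnitude admitted in the state transition; beyond it the
# linearization is meaningless and exp() would overflow/underflow.
.EKF_EXP_CAP <- 50

#' EKF time-update (prediction) step
#'
#' Propagates the state one step forward under the exponential-decay
#' transition `x1 <- x1 * exp(-x2 * dt_scale)` with `x2` and `x3` constant,
#' and the covariance through the transition Jacobian
#' `F = [[e^{-x2 s}, -s x1 e^{-x2 s}, 0], [0,1,0], [0,0,1]]` plus process
#' noise `Q = diag(sigma_v^2, 0, 0)`.
#'
#' @param state An [ekf_state()].
#' @param noise An [ekf_noise()].
#' @param dt_scale Step-length scale relative to the reference sampling
#'   interval the exponent `x2` was defined for (default 1; used for
#'   irregular sampling).
#' @return The prior `ekf_state` at the next step. If the exponent had to be
#'   capped to avoid overflow the result carries attribute `capped = TRUE`.
#' @export
ekf_predict <- function(state, noise, dt_scale = 1) {
  stopifnot(inherits(state, "ekf_state"), inherits(noise, "ekf_noise"))
  if (!is.finite(dt_scale) || dt_scale <= 0)
    stop("ekf_predict: dt_scale must be > 0")
  x <- state$x
  expo <- x[2] * dt_scale
  capped <- FALSE
  if (abs(expo) > .EKF_EXP_CAP) {
    expo <- sign(expo) * .EKF_EXP_CAP
    capped <- TRUE
  }
  decay <- exp(-expo)
  x1_new <- x[1] * decay
  Fk <- matrix(c(decay, -decay * x[1] * dt_scale, 0,
                 0, 1, 0,
                 0, 0, 1), nrow = 3, byrow = TRUE)
  Q <- diag(c(noise$sigma_v^2, 0, 0))
  P <- Fk %*% state$P %*% t(Fk) + Q
  P <- (P + t(P)) / 2
  out <- ekf_state(x1_new, x[2], x[3], P)
  if (capped) attr(out, "capped") <- TRUE
  out
}

#' EKF predicted observation
#'
#' The scalar measurement model: `zhat = x1 + x3` (remaining delta signal
#' plus terminal offset).
#'
#' @param state An [ekf_state()].
#' @return Predicted scalar observation.
#' @export
ekf_predict_observation <- function(state) {
  stopifnot(inherits(state, "ekf_state"))
  unname(state$x[1] + state$x[3])
}

#' EKF measurement-update step
#'
#' Standard Kalman update for the scalar observation `z` with measurement
#' row `H = (1, 0, 1)`: innovation covariance `S = H P H' + sigma_w^2`,
#' gain `K = P H'/S`, posterior mean `x + K (z - zhat)` and covariance
#' `(I - K H) P` (symmetrized).
#'
#' @param prior An [ekf_state()] (output of [ekf_predict()]).
#' @param z Measured scalar signal.
#' @param noise An [ekf_noise()].
#' @return Posterior `ekf_state` with attributes `innovation`, `gain`
#'   (3-vector) and `S`.
#' @export
ekf_update <- function(prior, z, noise) {
  stopifnot(inherits(prior, "ekf_state"), inherits(noise, "ekf_noise"))
  if (!is.finite(z)) stop("ekf_update: non-finite observation")
  H <- matrix(c(1, 0, 1), nrow = 1)
  P <- prior$P
  S <- drop(H %*% P %*% t(H)) + noise$sigma_w^2
  if (!is.finite(S) || S <= 0)
    stop("ekf_update: innovation covariance S <= 0 (covariance corrupted); S = ", S)
  K <- drop(P %*% t(H)) / S
  innov <- z - ekf_predict_observation(prior)
  x_new <- prior$x + K * innov
  P_new <- (diag(3) - K %*% H) %*% P
  P_new <- (P_new + t(P_new)) / 2
  out <- ekf_state(x_new[1], x_new[2], x_new[3], P_new)
  attr(out, "innovation") <- innov
  attr(out, "gain") <- K
  attr(out, "S") <- S
  out
}

#' Estimate the sensor-noise level from the first observations
#'
#' Standard deviation of the residuals of a linear detrend over the first
#' `n0` observations; used as the default `sigma_w` when none is supplied.
#'
#' @param z Numeric signal vector.
#' @param n0 Number of leading observations to use (default 10).
#' @return Estimated noise standard deviation (floored at a small positive
#'   value so the filter stays well-defined on noise-free input).
#' @export
estimate_sensor_noise <- function(z, n0 = 10) {
  n0 <- min(n0, length(z))
  if (n0 < 4) stop("estimate_sensor_noise: need at least 4 observations")
  zz <- z[seq_len(n0)]
  res <- stats::lm.fit(cbind(1, seq_len(n0)), zz)$residuals
  s <- stats::sd(res)
  max(s, 1e-6 * max(abs(zz), 1))
}

#' Default EKF initialization for a diafiltration signal
#'
#' Heuristic starting state built from the first observation `z0`: the
#' terminal offset `x3` starts at a DF-buffer blank signal when one is
#' available and otherwise at `z0 / 2`; the delta signal takes up the
#' remainder (`x1 = z0 - x3`); the exchange-rate exponent starts at
#' `kappa0 * F * dt / V` (free-passage prior `kappa0 = 1`) when the process
#' constants are known, else at `3 / n_obs` (about three e-folds over the
#' record). The initial covariance is diagonal with generous spreads
#' `(z0/2)^2` on the signal states and `x2^2` on the rate.
#'
#' @param z0 First observation.
#' @param dt Sampling interval (min), with `F` and `V` for the rate prior.
#' @param F,V Permeate flow (mL/min) and retentate volume (mL); optional.
#' @param kappa0 Prior sieving coefficient (default 1).
#' @param x3_0 Optional DF-buffer blank signal (terminal level).
#' @param n_obs Record length, used by the fallback rate prior.
#' @return An [ekf_state()].
#' @export
ekf_init <- function(z0, dt = NULL, F = NULL, V = NULL, kappa0 = 1,
                     x3_0 = NULL, n_obs = 300) {
  if (!is.finite(z0)) stop("ekf_init: z0 must be finite")
  x3 <- if (!is.null(x3_0)) x3_0 else 0.5 * z0
  x1 <- z0 - x3
  x2 <- if (!is.null(F) && !is.null(V) && !is.null(dt)) {
    kappa0 * F * dt / V
  } else {
    3 / n_obs
  }
  spread <- max(abs(0.5 * z0), 1e-3)
  P0 <- diag(c(spread^2, x2^2, spread^2))
  ekf_state(x1, x2, x3, P0)
}

#' Run the buffer-exchange EKF over an observation stream
#'
#' Alternates [ekf_predict()] and [ekf_update()] over a time-ordered scalar
#' signal. Irregular sampling is handled by rescaling the transition exponent
#' by `dt_k / dt_ref` where `dt_ref` is the median spacing; steps where this
#' rescaling was active (ratio differing from 1 by more than 1%) are flagged
#' in the trace.
#'
#' @param t Strictly increasing timestamps (min).
#' @param z Observed signal, same length as `t` (>= 2 finite values).
#' @param init Optional [ekf_state()]; default built by [ekf_init()].
#' @param noise Optional [ekf_noise()]; by default `sigma_w` is estimated
#'   from the first observations ([estimate_sensor_noise()]) and
#'   `sigma_v = 0.01 * sigma_w`.
#' @param F,V,kappa0,x3_0 Passed to [ekf_init()] when `init` is missing.
#' @param passes Number of filter passes (default 2). A single forward pass
#'   tends to freeze the rate state before it has converged: the early,
#'   information-rich observations are processed while the linearization
#'   point is still far off and are never revisited. With `passes > 1` the
#'   filter is re-run over the record, re-initialized from the previous
#'   pass's terminal rate and offset with a reset covariance; each pass is
#'   the unmodified predict/update recursion and the returned trace is the
#'   final pass. Use `passes = 1` for strictly streaming operation.
#' @return A data frame of class `ekf_trace` with one row per observation:
#'   `t`, `z`, `zhat` (one-step prediction), `innovation`, posterior `x1`,
#'   `x2`, `x3`, posterior variances `P11`, `P22`, `P33`, gains `K1`, `K2`,
#'   `K3`, `filtered` (posterior `x1 + x3`), and `dt_flag`. Attributes:
#'   `terminal` (final `ekf_state`), `noise`, `dt_ref`.
#' @examples
#' t <- 0:299
#' z <- 5 + 3 * exp(-0.05 * t)
#' tr <- run_filter(t, z)
#' tail(tr$x2, 1)  # ~ 0.05
#' @export
run_filter <- function(t, z, init = NULL, noise = NULL,
                       F = NULL, V = NULL, kappa0 = 1, x3_0 = NULL,
                       passes = 2) {
  n <- length(z)
  if (length(t) != n) stop("run_filter: t and z must have the same length")
  if (n < 2) stop("run_filter: need at least 2 observations")
  if (!all(is.finite(t)) || !all(is.finite(z)))
    stop("run_filter: non-finite observations; drop flagged values first")
  if (any(diff(t) <= 0)) stop("run_filter: timestamps must be strictly increasing")

  dt_ref <- stats::median(diff(t))
  if (is.null(noise)) {
    sw <- estimate_sensor_noise(z)
    noise <- ekf_noise(sigma_v = 0.01 * sw, sigma_w = sw)
  }
  if (is.null(init)) {
    init <- ekf_init(z[1], dt = dt_ref, F = F, V = V, kappa0 = kappa0,
                     x3_0 = x3_0, n_obs = n)
  }
  if (passes < 1) stop("run_filter: passes must be >= 1")
  if (passes > 1) {
    prev <- run_filter(t, z, init = init, noise = noise, passes = passes - 1)
    term <- attr(prev, "terminal")
    rng <- max(diff(range(z)), .Machine$double.eps)
    x2_start <- if (term$x[2] > 0) term$x[2] else init$x[2]
    init <- ekf_state(z[1] - term$x[3], x2_start, term$x[3],
                      diag(c((0.2 * rng)^2,
                             max((0.5 * x2_start)^2, 1e-12),
                             (0.2 * rng)^2)))
  }

  trace <- data.frame(t = t, z = z, zhat = NA_real_, innovation = NA_real_,
                      x1 = NA_real_, x2 = NA_real_, x3 = NA_real_,
                      P11 = NA_real_, P22 = NA_real_, P33 = NA_real_,
                      K1 = NA_real_, K2 = NA_real_, K3 = NA_real_,
                      filtered = NA_real_, dt_flag = FALSE)
  state <- init
  for (k in seq_len(n)) {
    if (k == 1L) {
      prior <- state
      s_k <- 1
    } else {
      s_k <- (t[k] - t[k - 1]) / dt_ref
      prior <- tryCatch(
        ekf_predict(state, noise, dt_scale = s_k),
        error = function(e) stop("run_filter: predict failed at step ", k,
                                 ": ", conditionMessage(e)))
    }
    zhat <- ekf_predict_observation(prior)
    post <- tryCatch(
      ekf_update(prior, z[k], noise),
      error = function(e) stop("run_filter: update failed at step ", k,
                               ": ", conditionMessage(e)))
    trace$zhat[k] <- zhat
    trace$innovation[k] <- attr(post, "innovation")
    trace[k, c("x1", "x2", "x3")] <- post$x
    trace[k, c("P11", "P22", "P33")] <- diag(post$P)
    trace[k, c("K1", "K2", "K3")] <- attr(post, "gain")
    trace$filtered[k] <- post$x[1] + post$x[3]
    trace$dt_flag[k] <- abs(s_k - 1) > 0.01
    state <- post
  }
  class(trace) <- c("ekf_trace", "data.frame")
  attr(trace, "terminal") <- state
  attr(trace, "noise") <- noise
  attr(trace, "dt_ref") <- dt_ref
  trace
}

#' Sieving-coefficient estimate from the EKF rate state
#'
#' Converts the per-step exchange-rate exponent `x2 = kappa * F * dt / V`
#' back to the sieving coefficient: `kappa = x2 * V / (F * dt)`. Values that
#' are not positive have no physical interpretation (the signal is not
#' decaying) and are flagged with a warning rather than clipped.
#'
#' @param x2 Exchange-rate exponent(s) from the filter.
#' @param F Permeate flow (mL/min), > 0.
#' @param V Retentate volume (mL), > 0.
#' @param dt Sampling interval the exponent refers to (min), > 0.
#' @return Sieving coefficient estimate(s).
#' @export
sieving_coefficient_from_state <- function(x2, F, V, dt) {
  if (!all(is.finite(c(F, V, dt))) || F <= 0 || V <= 0 || dt <= 0)
    stop("sieving_coefficient_from_state: F, V, dt must be > 0")
  kappa <- x2 * V / (F * dt)
  if (any(is.finite(kappa) & kappa <= 0))
    warning("sieving_coefficient_from_state: non-positive kappa estimate(s); ",
            "not physically meaningful")
  kappa
}

#' Summarize an EKF trace
#'
#' @param trace An `ekf_trace` from [run_filter()].
#' @param F,V,dt Optional process constants; when all given, the terminal
#'   sieving-coefficient estimate is included.
#' @return A list (JSON-ready) with the terminal state, its variances and
#'   optionally the terminal kappa estimate.
#' @export
filter_summary <- function(trace, F = NULL, V = NULL, dt = NULL) {
  stopifnot(inherits(trace, "ekf_trace"))
  term <- attr(trace, "terminal")
  out <- list(
    n_steps = nrow(trace),
    x1 = unname(term$x[1]), x2 = unname(term$x[2]), x3 = unname(term$x[3]),
    P_diag = unname(diag(term$P)),
    sigma_v = attr(trace, "noise")$sigma_v,
    sigma_w = attr(trace, "noise")$sigma_w,
    dt_ref = attr(trace, "dt_ref"))
  if (!is.null(F) && !is.null(V)) {
    if (is.null(dt)) dt <- attr(trace, "dt_ref")
    out$kappa <- suppressWarnings(
      sieving_coefficient_from_state(out$x2, F = F, V = V, dt = dt))
  }
  out
}
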