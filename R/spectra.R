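#' Time series of Raman spectra
#'
#' Container for an acquisition run: a time-by-wavenumber intensity matrix
#' with per-spectrum exposure metadata. Intensities are raw detector counts
#' until [normalize_exposure()] converts them to counts per second.
#'
#' @param wavenumbers Strictly increasing spectral axis (1/cm).
#' @param intensities Matrix, one row per spectrum, `length(wavenumbers)`
#'   columns; non-negative before baseline removal.
#' @param exposure_ms Per-spectrum exposure time (ms), > 0.
#' @param t Acquisition timestamps (min), strictly increasing.
#' @param accumulations Acquisitions averaged per spectrum (default 1).
#' @param unit `"counts"` or `"counts/s"`.
#' @return An object of class `spectrum_series`.
#' @export
spectrum_series <- function(wavenumbers, intensities, exposure_ms, t,
                            accumulations = 1, unit = "counts") {
  intensities <- as.matrix(intensities)
  n <- nrow(intensities)
  if (any(diff(wavenumbers) <= 0))
    stop("spectrum_series: wavenumber axis must be strictly increasing")
  if (ncol(intensities) != length(wavenumbers))
    stop("spectrum_series: intensity columns must match the wavenumber axis")
  exposure_ms <- rep_len(exposure_ms, n)
  accumulations <- rep_len(accumulations, n)
  if (length(t) != n) stop("spectrum_series: need one timestamp per spectrum")
  if (n > 1 && any(diff(t) <= 0))
    stop("spectrum_series: timestamps must be strictly increasing")
  if (any(exposure_ms <= 0)) stop("spectrum_series: exposure must be > 0")
  structure(list(wavenumbers = as.numeric(wavenumbers),
                 intensities = intensities,
                 exposure_ms = exposure_ms,
                 accumulations = accumulations,
                 t = as.numeric(t), unit = unit),
            class = "spectrum_series")
}

#' @export
print.spectrum_series <- function(x, ...) {
  cat("spectrum_series:", nrow(x$intensities), "spectra x",
      length(x$wavenumbers), "wavenumbers [",
      min(x$wavenumbers), "-", max(x$wavenumbers), "1/cm ], unit:", x$unit, "\n")
  invisible(x)
}

#' Normalize spectra by exposure time
#'
#' Divides each spectrum by its exposure time (s) times the number of
#' accumulations, yielding count rates that are comparable across the
#' step-wise exposure reductions used to avoid detector saturation.
#'
#' @param series A [spectrum_series()] in counts.
#' @return A `spectrum_series` in counts/s.
#' @export
normalize_exposure <- function(series) {
  stopifnot(inherits(series, "spectrum_series"))
  if (identical(series$unit, "counts/s"))
    stop("normalize_exposure: series already exposure-normalized")
  scale_s <- series$exposure_ms / 1000 * series$accumulations
  out <- series
  out$intensities <- series$intensities / scale_s
  out$unit <- "counts/s"
  out
}

#' Asymmetric Whittaker baseline estimation
#'
#' Asymmetric least squares: the baseline `b` minimizes
#' `sum(w_i (y_i - b_i)^2) + lambda * sum((D2 b)^2)` with weights reassigned
#' each iteration to `p` where the signal exceeds the baseline and `1 - p`
#' elsewhere, so peaks are ignored while the smooth background is followed.
#' Used for visualization and band reporting only, not before PLS/PCA
#' modelling (raw spectra calibrate better).
#'
#' @param y Spectrum intensities (length >= 10).
#' @param lambda Smoothness penalty (> 0; default 1e5).
#' @param p Asymmetry (0 < p < 1; default 1e-3). `p = 0.5` reduces to an
#'   ordinary Whittaker smoother.
#' @param max_iter Maximum reweighting iterations (default 20).
#' @return List with `baseline`, `corrected` (= y - baseline), `iterations`
#'   and logical `converged` (weights stable before `max_iter`).
#' @export
whittaker_baseline <- function(y, lambda = 1e5, p = 1e-3, max_iter = 20) {
  m <- length(y)
  if (m < 10) stop("whittaker_baseline: spectrum too short (< 10 points)")
  if (lambda <= 0) stop("whittaker_baseline: lambda must be > 0")
  if (p <= 0 || p >= 1) stop("whittaker_baseline: p must be in (0, 1)")
  D <- Matrix::bandSparse(m - 2, m, k = 0:2,
                          diagonals = list(rep(1, m - 2), rep(-2, m - 2),
                                           rep(1, m - 2)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    W <- Matrix::Diagonal(m, w)
    z <- as.numeric(Matrix::solve(W + DtD, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (all(w_new == w)) {
      converged <- TRUE
      break
    }
    w <- w_new
  }
  if (!converged)
    warning("whittaker_baseline: weights not settled after ", max_iter,
            " iterations")
  list(baseline = z, corrected = y - z, iterations = iter,
       converged = converged)
}

#' Savitzky-Golay spectral smoothing
#'
#' 15-point, second-order, zero-derivative Savitzky-Golay filter: local
#' quadratic fits that preserve polynomial signals up to order 2 exactly
#' while attenuating high-frequency noise.
#'
#' @param y Spectrum (length >= window).
#' @param n Window length (odd, default 15).
#' @param order Polynomial order (default 2).
#' @return Smoothed spectrum, same length.
#' @export
savgol_smooth <- function(y, n = 15, order = 2) {
  if (length(y) < n)
    stop("savgol_smooth: spectrum shorter than the filter window")
  signal::sgolayfilt(y, p = order, n = n, m = 0)
}

# Core PLS fit: mixOmics NIPALS engine, results reduced to plain matrices.
# Returns xbar, ybar, W (weights), P (X loadings), q (y loadings),
# R = W (P'W)^-1 (projection), B = R q (regression vector), lambda
# (per-component score variances).
.pls_core <- function(X, y, ncomp) {
  fit <- withCallingHandlers(
    mixOmics::pls(X, as.matrix(y), ncomp = ncomp, scale = FALSE,
                  mode = "regression"),
    # constant (all-zero) wavenumber columns trip an sd == 0 warning in the
    # engine's screening correlations; they are harmless for the fit
    warning = function(w) {
      if (grepl("standard deviation is zero", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  W <- unname(fit$loadings$X)
  Tsc <- unname(fit$variates$X)
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2, xbar)
  yc <- y - ybar
  G <- solve(crossprod(Tsc))
  P <- t(G %*% crossprod(Tsc, Xc))          # p x A
  q <- drop(G %*% crossprod(Tsc, yc))       # A
  R <- W %*% solve(crossprod(P, W))         # p x A
  B <- drop(R %*% q)
  lambda <- colSums(Tsc^2) / (nrow(X) - 1)
  list(xbar = xbar, ybar = ybar, W = W, P = P, q = q, R = R, B = B,
       scores = Tsc, lambda = lambda)
}

.pls_predict_core <- function(core, Xnew) {
  Xc <- sweep(Xnew, 2, core$xbar)
  Tn <- Xc %*% core$R
  pred <- drop(core$ybar + Xc %*% core$B)
  resid <- Xc - Tn %*% t(core$P)
  list(pred = pred, scores = Tn, Q = rowSums(resid^2))
}

#' Fit a mean-centered PLS concentration model
#'
#' Partial-least-squares regression of analyte concentration on raw
#' (exposure-normalized) spectra. Mean centering only — no scaling, no
#' wavelength selection, no derivative preprocessing. Cross-validated
#' root-mean-square error (RMSECV) is reported, and Hotelling T^2 and
#' Q-residual (distance to the model hyperplane) limits are stored for
#' outlier rejection at prediction time. `level` is the family-wise flag
#' level for the combined (T^2 or Q) outlier test; each statistic uses a
#' Bonferroni-split confidence level.
#'
#' @param spectra A [spectrum_series()] or a numeric matrix (rows =
#'   calibration spectra).
#' @param concentrations Reference concentrations, one per spectrum; must
#'   not be constant.
#' @param n_components Number of latent variables (>= 1, less than the
#'   number of calibration samples minus one).
#' @param cv `"loo"` (leave-one-out, default for n <= 25) or `"venetian"`
#'   (7-fold venetian blinds).
#' @param level Family-wise outlier-flag level (default 0.95).
#' @return An object of class `pls_model` holding the centering vectors,
#'   weights/loadings, regression vector, `rmsecv`, `t2_limit`, `q_limit`.
#' @export
fit_pls <- function(spectra, concentrations, n_components,
                    cv = NULL, level = 0.95) {
  X <- if (inherits(spectra, "spectrum_series")) spectra$intensities
       else as.matrix(spectra)
  axis <- if (inherits(spectra, "spectrum_series")) spectra$wavenumbers
          else seq_len(ncol(X))
  y <- as.numeric(concentrations)
  n <- nrow(X)
  if (length(y) != n) stop("fit_pls: one concentration per spectrum required")
  if (stats::sd(y) == 0) stop("fit_pls: constant concentrations; nothing to model")
  A <- as.integer(n_components)
  if (A < 1 || A >= min(n, ncol(X)))
    stop("fit_pls: n_components must be >= 1 and < min(n_samples, n_wavenumbers)")
  if (n < A + 2) stop("fit_pls: need at least n_components + 2 samples")

  core <- .pls_core(X, y, A)

  # cross-validated error
  if (is.null(cv)) cv <- if (n <= 25) "loo" else "venetian"
  folds <- if (cv == "loo") seq_len(n) else ((seq_len(n) - 1L) %% 7L) + 1L
  press <- 0
  q_cv <- numeric(n)
  for (f in unique(folds)) {
    hold <- folds == f
    core_f <- .pls_core(X[!hold, , drop = FALSE], y[!hold], A)
    pr_f <- .pls_predict_core(core_f, X[hold, , drop = FALSE])
    press <- press + sum((pr_f$pred - y[hold])^2)
    q_cv[hold] <- pr_f$Q
  }
  rmsecv <- sqrt(press / n)

  # calibration statistics and outlier limits (Bonferroni over T2 and Q)
  alpha_each <- 1 - (1 - level) / 2
  # T2 limit in its prediction form (flags are applied to new spectra);
  # Q limit from the cross-validated residuals: fitted calibration residuals
  # are deflated by the fit, which makes the usual moment-matched limit far
  # too tight in high dimension, while held-out residuals estimate the
  # new-sample Q distribution directly.
  t2_limit <- A * (n^2 - 1) / (n * (n - A)) * stats::qf(alpha_each, A, n - A)
  qm <- mean(q_cv)
  qv <- stats::var(q_cv)
  eps_q <- (1e-8 * mean(rowSums(sweep(X, 2, core$xbar)^2)))
  if (qm <= eps_q || qv <= eps_q^2) {
    # (near-)noiseless calibration: residual subspace is empty in practice
    q_limit <- max(q_cv) * 2 + eps_q
  } else {
    g <- qv / (2 * qm)
    h <- 2 * qm^2 / qv
    q_limit <- g * stats::qchisq(alpha_each, h)
  }

  structure(list(
    wavenumbers = axis, n_components = A, n_samples = n,
    xbar = core$xbar, ybar = core$ybar,
    W = core$W, P = core$P, q = core$q, R = core$R, B = core$B,
    lambda = core$lambda, rmsecv = rmsecv, cv = cv, level = level,
    t2_limit = t2_limit, q_limit = q_limit,
    y_range = range(y)), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("PLS model:", x$n_components, "component(s),", x$n_samples,
      "calibration spectra\n")
  cat("RMSECV:", signif(x$rmsecv, 4), "(", x$cv, ")  T2 limit:",
      signif(x$t2_limit, 4), " Q limit:", signif(x$q_limit, 4), "\n")
  invisible(x)
}

#' Predict concentration from a spectrum with outlier diagnostics
#'
#' Projects a new (exposure-normalized) spectrum into the PLS model and
#' returns the predicted concentration together with its Hotelling T^2
#' statistic, Q residual (squared distance to the model hyperplane) and an
#' outlier flag set when either statistic exceeds its calibration limit.
#'
#' @param model A [fit_pls()] model.
#' @param spectrum Numeric vector on the model's wavenumber axis, or a
#'   matrix / [spectrum_series()] of such spectra.
#' @return Data frame with `concentration`, `t2`, `q_residual`, `outlier`.
#' @export
predict_concentration <- function(model, spectrum) {
  stopifnot(inherits(model, "pls_model"))
  if (inherits(spectrum, "spectrum_series")) {
    if (length(spectrum$wavenumbers) != length(model$wavenumbers) ||
        max(abs(spectrum$wavenumbers - model$wavenumbers)) > 1e-6)
      stop("predict_concentration: wavenumber axis does not match the model")
    X <- spectrum$intensities
  } else {
    X <- if (is.matrix(spectrum)) spectrum else matrix(spectrum, nrow = 1)
    if (ncol(X) != length(model$wavenumbers))
      stop("predict_concentration: spectrum length does not match the model axis")
  }
  pr <- .pls_predict_core(model, X)
  t2 <- rowSums(sweep(pr$scores^2, 2, model$lambda, "/"))
  data.frame(concentration = pr$pred, t2 = t2, q_residual = pr$Q,
             outlier = t2 > model$t2_limit | pr$Q > model$q_limit)
}

# R^2 of a single-exponential (a * exp(-b t) + c) fit to a score series.
.exp_fit_r2 <- function(t, s) {
  tt <- t - t[1]
  n <- length(s)
  tail_mean <- mean(s[max(1, n - max(3, n %/% 10)):n])
  a0 <- s[1] - tail_mean
  if (abs(a0) < 1e-12 * max(abs(s), 1)) return(list(r2 = NA_real_, rate = NA_real_))
  b0 <- 3 / max(tt)
  fit <- tryCatch(
    minpack.lm::nlsLM(s ~ a * exp(-b * tt) + c,
                      start = list(a = a0, b = b0, c = tail_mean),
                      lower = c(-Inf, 0, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(r2 = NA_real_, rate = NA_real_))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((s - mean(s))^2)
  list(r2 = 1 - ss_res / ss_tot, rate = unname(stats::coef(fit)["b"]))
}

#' Extract the normalized buffer-exchange score from DF-phase spectra
#'
#' Mean-centered PCA over the diafiltration-phase spectra; the component
#' carrying the buffer-exchange variability is selected as the one (among
#' the first `max_pc`) whose score series best follows a single exponential
#' decay (highest R^2 of an exponential fit), with ties broken by explained
#' variance. The selected score is min-max normalized over the observed
#' window and oriented so that it decreases towards DF completion. The
#' result is the scalar input stream for [run_filter()].
#'
#' @param series A [spectrum_series()] (exposure-normalized).
#' @param component Optional manual override: principal-component index.
#' @param max_pc Number of leading components considered (default 5).
#' @param min_r2 Minimum exponential-fit R^2 for automatic selection
#'   (default 0.5); below it selection fails with a diagnostic listing the
#'   candidates.
#' @return Data frame of class `buffer_score_series` with columns `t`,
#'   `score`; attributes `component_index`, `explained_variance`, `fit_r2`.
#' @export
pca_buffer_signal <- function(series, component = NULL, max_pc = 5,
                              min_r2 = 0.5) {
  stopifnot(inherits(series, "spectrum_series"))
  X <- series$intensities
  if (nrow(X) < 10)
    stop("pca_buffer_signal: need >= 10 spectra spanning part of the DF phase")
  col_sd <- apply(X, 2, stats::sd)
  if (max(col_sd) <= 1e-12 * max(abs(X)))
    stop("pca_buffer_signal: spectra show no time variation (no exchange variability)")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  npc <- min(max_pc, ncol(pc$x))
  expl <- pc$sdev^2 / sum(pc$sdev^2)

  if (is.null(component)) {
    fits <- lapply(seq_len(npc), function(j) .exp_fit_r2(series$t, pc$x[, j]))
    r2s <- vapply(fits, `[[`, numeric(1), "r2")
    if (all(is.na(r2s)) || max(r2s, na.rm = TRUE) < min_r2) {
      stop("pca_buffer_signal: no principal component follows an exponential ",
           "exchange profile; candidate R^2: ",
           paste(sprintf("PC%d=%.3f", seq_len(npc), r2s), collapse = ", "))
    }
    best_r2 <- max(r2s, na.rm = TRUE)
    tied <- which(!is.na(r2s) & r2s >= best_r2 - 1e-6)
    component <- tied[which.max(expl[tied])]
    fit_r2 <- r2s[component]
  } else {
    if (component < 1 || component > ncol(pc$x))
      stop("pca_buffer_signal: component index out of range")
    fit_r2 <- .exp_fit_r2(series$t, pc$x[, component])$r2
  }

  s <- pc$x[, component]
  rng <- range(s)
  score <- (s - rng[1]) / (rng[2] - rng[1])
  n <- length(score)
  head_n <- max(1, round(0.1 * n))
  if (mean(score[seq_len(head_n)]) < mean(score[(n - head_n + 1):n]))
    score <- 1 - score
  out <- data.frame(t = series$t, score = score)
  class(out) <- c("buffer_score_series", "data.frame")
  attr(out, "component_index") <- component
  attr(out, "explained_variance") <- expl[component]
  attr(out, "fit_r2") <- fit_r2
  out
}

#' Read / write a spectral matrix CSV
#'
#' Layout: first column `t` (min), second `exposure_ms`, remaining columns
#' one per wavenumber with the wavenumber as header.
#'
#' @param path CSV file path.
#' @param accumulations Acquisitions per spectrum (not stored in the CSV).
#' @param unit Intensity unit of the stored matrix.
#' @return `read_spectra_csv`: a [spectrum_series()].
#' @export
read_spectra_csv <- function(path, accumulations = 1, unit = "counts") {
  d <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  wn <- as.numeric(names(d)[-(1:2)])
  spectrum_series(wavenumbers = wn,
                  intensities = as.matrix(d[, -(1:2), drop = FALSE]),
                  exposure_ms = d[[2]], t = d[[1]],
                  accumulations = accumulations, unit = unit)
}

#' @rdname read_spectra_csv
#' @param series A [spectrum_series()] to write.
#' @param header Optional provenance lines (written prefixed with `#`).
#' @export
write_spectra_csv <- function(series, path, header = NULL) {
  stopifnot(inherits(series, "spectrum_series"))
  d <- data.frame(t = series$t, exposure_ms = series$exposure_ms,
                  series$intensities, check.names = FALSE)
  names(d) <- c("t", "exposure_ms", format(series$wavenumbers, trim = TRUE))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(d, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Persist / load a PLS model as JSON
#'
#' @param model A [fit_pls()] model.
#' @param path JSON file path.
#' @return `read_pls_json`: the restored `pls_model`.
#' @export
write_pls_json <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  obj <- lapply(unclass(model), function(v) if (is.matrix(v)) unclass(v) else v)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pls_json
#' @export
read_pls_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("W", "P", "R")) obj[[nm]] <- as.matrix(obj[[nm]])
  obj$xbar <- as.numeric(obj$xbar)
  structure(obj, class = "pls_model")
}
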