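test_that("exposure normalization is scale invariant and has the right units", {
  wn <- seq(300, 3100, by = 10)
  base <- matrix(rep(seq_along(wn), each = 2), nrow = 2, byrow = FALSE)
  s1 <- spectrum_series(wn, base, exposure_ms = c(800, 400), t = c(0, 1))
  s2 <- spectrum_series(wn, base * c(1, 0.5), exposure_ms = c(800, 400),
                        t = c(0, 1))
  n2 <- normalize_exposure(s2)
  expect_equal(n2$intensities[1, ] * (400 / 800) / 1, n2$intensities[2, ] * 0.5)
  # 800 counts at 800 ms, 1 accumulation -> 1000 counts/s
  s3 <- spectrum_series(wn, matrix(800, 1, length(wn)), 800, 0)
  expect_equal(unname(normalize_exposure(s3)$intensities[1, 1]), 1000)
  expect_error(normalize_exposure(normalize_exposure(s3)), "already")
  expect_error(spectrum_series(wn, base, c(0, 800), c(0, 1)), "exposure")
})

test_that("the asymmetric baseline hugs smooth backgrounds but not peaks", {
  x <- seq_len(500)
  flat <- rep(3, 500)
  bf <- whittaker_baseline(flat)
  expect_equal(bf$baseline, flat, tolerance = 1e-6)
  expect_lt(max(abs(bf$corrected)), 1e-6)

  ramp <- 2 + 0.01 * x
  peak <- 5 * exp(-(x - 250)^2 / (2 * 10^2))
  bl <- whittaker_baseline(ramp + peak, lambda = 1e5, p = 1e-3)
  height <- (ramp + peak - bl$baseline)[250]
  expect_lt(abs(height - 5) / 5, 0.02)

  # p = 0.5 reduces to the ordinary (symmetric) Whittaker smoother
  set.seed(2)
  y <- sin(x / 50) + rnorm(500, 0, 0.1)
  sym <- suppressWarnings(whittaker_baseline(y, lambda = 100, p = 0.5))
  D <- diff(diag(500), differences = 2)
  plain <- solve(diag(500) + 2 * 100 * crossprod(D), y)
  expect_equal(sym$baseline, as.numeric(plain), tolerance = 1e-8)
})

test_that("Savitzky-Golay smoothing reproduces quadratics and attenuates noise", {
  x <- seq(0, 10, length.out = 200)
  quad <- 2 + 3 * x - 0.5 * x^2
  expect_equal(savgol_smooth(quad), quad, tolerance = 1e-10)
  expect_equal(savgol_smooth(rep(4, 50)), rep(4, 50))
  set.seed(4)
  noise <- rnorm(5000)
  sm <- savgol_smooth(noise)
  # central-point variance equals the sum of squared filter weights
  w <- signal::sgolay(p = 2, n = 15)[8, ]
  expect_equal(var(sm[16:4985]), sum(w^2), tolerance = 0.1)
  expect_lt(var(sm), 1)
  expect_error(savgol_smooth(rnorm(10)), "window")
})

test_that("PLS on rank-1 noiseless spectra is exact and equals OLS on the score", {
  y <- seq(1, 10, length.out = 12)
  sp <- make_spectra(12, noise = 0, c1 = y, c2 = rep(0, 12))
  mod <- fit_pls(sp$X, y, n_components = 1)
  expect_lt(mod$rmsecv / diff(range(y)), 1e-6)
  pred <- predict_concentration(mod, sp$X)
  expect_equal(pred$concentration, y, tolerance = 1e-8)
  expect_false(any(pred$outlier))

  # dual route: OLS of y on the first PLS score
  Xc <- sweep(sp$X, 2, mod$xbar)
  score <- drop(Xc %*% mod$R[, 1])
  ols <- lm(y ~ score)
  expect_equal(unname(fitted(ols)), pred$concentration, tolerance = 1e-8)
})

test_that("PLS handles overlapping components under noise and rejects bad inputs", {
  set.seed(13)
  sp <- make_spectra(40, noise = 0.005)  # 0.5% of max intensity
  mod <- fit_pls(sp$X, sp$y, n_components = 2)
  expect_lt(mod$rmsecv / diff(range(sp$y)), 0.02)
  expect_error(fit_pls(sp$X[1:5, ], sp$y[1:5], n_components = 5), "n_components")
  expect_error(fit_pls(sp$X, rep(1, 40), n_components = 2), "constant")
})

test_that("spiked and out-of-cloud spectra are flagged by T2/Q diagnostics", {
  set.seed(17)
  sp <- make_spectra(40, noise = 0.005)
  mod <- fit_pls(sp$X, sp$y, n_components = 2)
  clean <- make_spectra(1, noise = 0.005)
  spiked <- clean$X
  spiked[1, 400] <- spiked[1, 400] + 0.2
  expect_true(predict_concentration(mod, spiked)$outlier)
  expect_gt(predict_concentration(mod, spiked)$q_residual,
            predict_concentration(mod, clean$X)$q_residual)
  # all-zero spectrum sits far outside the calibration cloud
  expect_true(predict_concentration(mod, numeric(length(sp$wn)))$outlier)
  expect_error(predict_concentration(mod, numeric(10)), "length")
})

test_that("PLS models persist to JSON and back without losing predictions", {
  set.seed(19)
  sp <- make_spectra(20, noise = 0.005)
  mod <- fit_pls(sp$X, sp$y, n_components = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_pls_json(mod, path)
  back <- read_pls_json(path)
  p1 <- predict_concentration(mod, sp$X)
  p2 <- predict_concentration(back, sp$X)
  expect_equal(p2$concentration, p1$concentration, tolerance = 1e-10)
  expect_equal(back$q_limit, mod$q_limit, tolerance = 1e-12)
})

test_that("the PCA buffer score tracks the decaying species and is oriented downward", {
  truth <- simulate_process(mini_df_recipe(), dt = 0.5)
  raman <- synthesize_raman(truth, mini_library(), noise_level = 0.5, seed = 23)
  rs <- normalize_exposure(raman)
  dfr <- startsWith(truth$phase, "DF")
  ds <- spectrum_series(rs$wavenumbers, rs$intensities[dfr, ],
                        rs$exposure_ms[dfr], rs$t[dfr],
                        accumulations = rs$accumulations[dfr], unit = rs$unit)
  sc <- pca_buffer_signal(ds)
  expect_gt(abs(cor(sc$score, truth$c_citrate[dfr])), 0.999)
  n <- nrow(sc)
  h <- max(1, round(0.1 * n))
  expect_gt(mean(sc$score[1:h]), mean(sc$score[(n - h + 1):n]))
  expect_true(all(sc$score >= -0.2 & sc$score <= 1.2))
  expect_true(attr(sc, "component_index") >= 1)

  # global intensity rescaling does not change the normalized score
  ds2 <- ds
  ds2$intensities <- ds$intensities * 3.7
  sc2 <- pca_buffer_signal(ds2)
  expect_equal(sc2$score, sc$score, tolerance = 1e-8)

  # no time variation -> explicit failure
  flat <- spectrum_series(ds$wavenumbers,
                          matrix(rep(ds$intensities[1, ], 12), 12, byrow = TRUE),
                          800, seq_len(12))
  expect_error(pca_buffer_signal(flat), "no time variation|variability")
})

test_that("spectral CSV round-trips the time/exposure/wavenumber layout", {
  wn <- seq(300, 3100, by = 50)
  set.seed(29)
  s <- spectrum_series(wn, matrix(runif(3 * length(wn)), 3), c(800, 800, 400),
                       t = c(0, 1, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(s, path, header = "roundtrip")
  back <- read_spectra_csv(path)
  expect_equal(back$wavenumbers, s$wavenumbers)
  expect_equal(unname(back$intensities), unname(s$intensities), tolerance = 1e-12)
  expect_equal(back$exposure_ms, s$exposure_ms)
})
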