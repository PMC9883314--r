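test_that("prediction decays the delta signal and propagates covariance through the Jacobian", {
  noise <- ekf_noise(sigma_v = 0, sigma_w = 1)
  s0 <- ekf_state(2, 0, 5, diag(3))
  expect_equal(ekf_predict(s0, noise)$x[["x1"]], 2)
  s1 <- ekf_state(2, 0.1, 5, diag(3))
  expect_equal(ekf_predict(s1, noise)$x[["x1"]], 2 * exp(-0.1), tolerance = 1e-9)

  # certain state stays certain without process noise
  s2 <- ekf_state(2, 0.1, 5, matrix(0, 3, 3))
  expect_equal(max(abs(ekf_predict(s2, noise)$P)), 0)

  # covariance row against a finite-difference Jacobian of the transition
  f <- function(x) c(x[1] * exp(-x[2]), x[2], x[3])
  x0 <- c(2, 0.1, 5)
  eps <- 1e-7
  J <- sapply(1:3, function(j) {
    xp <- x0; xp[j] <- xp[j] + eps
    (f(xp) - f(x0)) / eps
  })
  P0 <- diag(c(0.5, 0.2, 0.3))
  pred <- ekf_predict(ekf_state(x0[1], x0[2], x0[3], P0), noise)
  expect_equal(pred$P, J %*% P0 %*% t(J), tolerance = 1e-6)
})

test_that("the observation model sums delta signal and offset", {
  expect_equal(ekf_predict_observation(ekf_state(2, 0.1, 5, diag(3))), 7.0)
  expect_equal(ekf_predict_observation(ekf_state(0, 3, 5, diag(3))), 5.0)
  expect_equal(ekf_predict_observation(ekf_state(-3, 0, 10, diag(3))), 7.0)
})

test_that("the measurement update matches dense matrix arithmetic and shrinks uncertainty", {
  noise <- ekf_noise(0, 1)
  prior <- ekf_state(1, 0.1, 4, diag(3))
  post <- ekf_update(prior, 6, noise)
  # S = 3, K = (1/3, 0, 1/3): filtered moves 2/3 of the innovation
  expect_equal(attr(post, "S"), 3)
  expect_equal(attr(post, "gain"), c(1 / 3, 0, 1 / 3))
  expect_equal(post$x[["x1"]] + post$x[["x3"]], 5 + (2 / 3) * (6 - 5))
  ref <- dense_ekf_update(c(1, 0.1, 4), diag(3), 6, 1)
  expect_equal(unname(post$x), unname(ref$x), tolerance = 1e-12)
  expect_equal(post$P, ref$P, tolerance = 1e-12)

  # huge sensor noise: measurement carries no information
  post2 <- ekf_update(prior, 100, ekf_noise(0, 1e12))
  expect_equal(unname(post2$x), c(1, 0.1, 4), tolerance = 1e-6)

  # zero innovation: mean unchanged, covariance still shrinks
  post3 <- ekf_update(prior, 5, noise)
  expect_equal(unname(post3$x), c(1, 0.1, 4))
  expect_true(sum(diag(post3$P)) < sum(diag(prior$P)))

  # posterior innovation never exceeds the prior innovation
  for (z in c(-2, 5.5, 9)) {
    p <- ekf_update(prior, z, noise)
    expect_lte(abs(z - (p$x[1] + p$x[3])), abs(z - 5))
  }
})

test_that("with a known fixed rate the EKF reduces to a linear Kalman filter", {
  set.seed(11)
  a <- exp(-0.05)
  z <- 5 + 3 * 0.95^(0:199) + rnorm(200, 0, 0.1)
  init <- ekf_state(3, 0.05, 5, diag(c(4, 0, 4)))  # no rate uncertainty
  tr <- run_filter(0:199, z, init = init, noise = ekf_noise(0.01, 0.1),
                   passes = 1)
  ref <- linear_kf(z, a, c(3, 5), diag(c(4, 4)), 0.01, 0.1)
  expect_equal(tr$filtered, ref, tolerance = 1e-9)
  expect_true(all(abs(tr$x2 - 0.05) < 1e-12))
})

test_that("covariance stays symmetric positive semi-definite over long runs", {
  set.seed(3)
  n <- 10000
  z <- 2 + 8 * exp(-0.002 * (0:(n - 1))) + rnorm(n, 0, 0.05)
  tr <- run_filter(seq_len(n), z, passes = 1)
  term <- attr(tr, "terminal")
  expect_equal(term$P, t(term$P))
  ev <- eigen(term$P, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10 * sum(diag(term$P)))
  expect_true(all(is.finite(tr$filtered)))
})

test_that("the filter recovers rate and offset of clean and noisy exponentials", {
  t <- 0:399
  z <- 5 + 3 * exp(-0.05 * t)
  tr <- run_filter(t, z, noise = ekf_noise(1e-5, 1e-3), F = 4.5, V = 45)
  expect_lt(abs(tail(tr$x2, 1) - 0.05) / 0.05, 0.02)
  expect_lt(abs(tail(tr$x3, 1) - 5), 0.05)

  # constant input: filtered output converges to the constant
  zc <- rep(4, 100)
  trc <- run_filter(1:100, zc + c(1e-9, numeric(99)))
  expect_equal(tail(trc$filtered, 1), 4, tolerance = 1e-3)

  # parameter recovery across 50 seeded noisy runs (noise 5% of range)
  rate_err <- offset_err <- numeric(50)
  for (s in 1:50) {
    set.seed(s)
    zn <- 5 + 3 * exp(-0.05 * (0:299)) + rnorm(300, 0, 0.15)
    trn <- run_filter(0:299, zn)
    rate_err[s] <- abs(tail(trn$x2, 1) - 0.05) / 0.05
    offset_err[s] <- abs(tail(trn$x3, 1) - 5) / 3
  }
  expect_lt(median(rate_err), 0.05)
  expect_lt(median(offset_err), 0.02)
})

test_that("filtering is equivariant under affine rescaling of the signal", {
  set.seed(21)
  t <- 0:199
  z <- 5 + 3 * exp(-0.04 * t) + rnorm(200, 0, 0.05)
  a <- 12.5; b <- -40
  init <- ekf_init(z[1], dt = 1, F = 4.5, V = 45)
  # rescale covariance consistently: scale signal rows/cols by a
  Dm <- diag(c(a, 1, a))
  init2 <- ekf_state(a * init$x[1], init$x[2], a * init$x[3] + b,
                     Dm %*% init$P %*% Dm)
  n1 <- ekf_noise(0.001, 0.05)
  n2 <- ekf_noise(0.001 * a, 0.05 * a)
  tr1 <- run_filter(t, z, init = init, noise = n1, passes = 1)
  tr2 <- run_filter(t, a * z + b, init = init2, noise = n2, passes = 1)
  expect_equal(tr2$filtered, a * tr1$filtered + b, tolerance = 1e-9)
})

test_that("kappa back-calculation inverts the rate exponent and flags non-physical values", {
  expect_equal(sieving_coefficient_from_state(0.1, F = 4.5, V = 45, dt = 1), 1.0)
  expect_warning(k0 <- sieving_coefficient_from_state(0, 4.5, 45, 1),
                 "non-physical|non-positive")
  expect_equal(k0, 0)
  expect_error(sieving_coefficient_from_state(0.1, F = 0, V = 45, dt = 1))
})

test_that("filter traces have one record per observation and serialize", {
  t <- 0:99
  z <- 2 + exp(-0.03 * t)
  tr <- run_filter(t, z)
  expect_s3_class(tr, "ekf_trace")
  expect_identical(nrow(tr), 100L)
  expect_true(all(!is.na(tr$filtered)))
  sm <- filter_summary(tr, F = 4.5, V = 45, dt = 1)
  expect_true(is.numeric(sm$kappa))
  expect_error(run_filter(c(1, 2, 2.5, 2.5), c(1, 2, 3, 4)), "increasing")
  expect_error(run_filter(1, 1), "at least 2")
})
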