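test_that("the transition likelihood matches the scalar closed form", {
  a <- -0.7; q <- 1.3; d <- 0.9; y0 <- 0.4; y1 <- -0.2
  data <- irregular_ts(c(0, d), matrix(c(y0, y1), 2, 1))
  par <- ctdyn:::par_encode(matrix(a), matrix(q))
  vd <- q * (1 - exp(2 * a * d)) / (-2 * a)
  expect_equal(ct_loglik(par, data),
               dnorm(y1, mean = exp(a * d) * y0, sd = sqrt(vd), log = TRUE),
               tolerance = 1e-10)
})

test_that("the likelihood is invariant to the time origin", {
  m <- random_ct_model(3, seed = 1)
  y <- sample_ou_path(m, esm_schedule(10, 5, 13, seed = 1), seed = 2)
  par <- ctdyn:::par_encode(m$drift, m$diffusion)
  shifted <- irregular_ts(y$times + 137.5, y$values, y$labels)
  expect_equal(ct_loglik(par, y), ct_loglik(par, shifted),
               tolerance = 1e-12)
})

test_that("for equal intervals the CT likelihood equals the exact DT likelihood", {
  m <- random_ct_model(3, seed = 2)
  d <- 0.75
  y <- sample_ou_path(m, seq(0, by = d, length.out = 120), seed = 3)
  par <- ctdyn:::par_encode(m$drift, m$diffusion)
  Phi <- lagged_params(m, d)
  Psi <- residual_cov(m, d)
  # independent route: sum of multivariate normal log densities in R
  ll_dt <- 0
  for (i in 2:120) {
    r <- y$values[i, ] - Phi %*% y$values[i - 1, ]
    ll_dt <- ll_dt + ctdyn:::mvn_logdens(r, Psi)
  }
  expect_equal(ct_loglik(par, y), ll_dt, tolerance = 1e-8)
})

test_that("the true parameters dominate perturbed ones on simulated data", {
  m <- random_ct_model(3, seed = 4, margin = 0.3)
  par_true <- ctdyn:::par_encode(m$drift, m$diffusion)
  for (seed in 1:5) {
    y <- sample_ou_path(m, esm_schedule(120, 6, 13.5, seed = seed),
                        seed = 100 + seed)
    par_bad <- par_true
    par_bad[2] <- par_bad[2] + 0.5   # one drift entry off by +0.5
    expect_gt(ct_loglik(par_true, y), ct_loglik(par_bad, y))
  }
})

test_that("unusable data are rejected with informative errors", {
  expect_error(irregular_ts(c(0, 1, 1, 2), matrix(0, 4, 2)), "increasing")
  y <- irregular_ts(c(0, 1), matrix(c(1, NA, 2, 3), 2, 2))
  expect_error(ctdyn:::transition_pairs(y), "no usable")
})

test_that("maximum likelihood recovers the drift on an irregular schedule", {
  A <- random_stable_drift(3, seed = 21, spectral_margin = 0.3, scale = 0.3)
  m <- ct_model(A, diffusion = diag(3))
  y <- sample_ou_path(m, esm_schedule(120, 6, 13.5, seed = 5), seed = 6)
  fit <- fit_ct_var(y, n_starts = 2, seed = 7)
  expect_true(fit$converged)
  expect_s3_class(fit$model, "ctmodel")
  se <- matrix(sqrt(diag(fit$vcov))[1:9], 3, 3)
  expect_true(all(abs(fit$model$drift - A) < 3.5 * se))
  expect_equal(fit$n_pairs, length(y$times) - 1L)
  expect_lt(fit$loglik, 0)
})

test_that("pooled OLS recovers a discrete-time model on equal intervals", {
  set.seed(8)
  Phi <- matrix(c(0.5, 0.15, -0.1, 0.4), 2, 2)
  Psi <- diag(0.5, 2)
  n <- 2000
  Y <- matrix(0, n, 2)
  for (i in 2:n)
    Y[i, ] <- Phi %*% Y[i - 1, ] + MASS::mvrnorm(1, c(0, 0), Psi)
  fit <- fit_dt_var(irregular_ts(seq_len(n), Y))
  expect_true(all(abs(fit$model$lagged - Phi) < 3 * fit$coef_se))
  expect_lt(max(abs(fit$model$residual_cov - Psi)), 0.1)
  expect_equal(fit$model$interval, 1)

  # a constant column makes the regression rank deficient
  Yc <- cbind(Y[, 1], 1)
  expect_error(fit_dt_var(irregular_ts(seq_len(n), Yc)), "rank deficient")
})

test_that("OLS standard errors match lm() per equation", {
  set.seed(9)
  Y <- matrix(rnorm(300), 100, 3)
  y <- irregular_ts(seq_len(100), Y, c("a", "b", "c"))
  fit <- fit_dt_var(y)
  ref <- lm(Y[-1, 2] ~ Y[-100, ])
  expect_equal(unname(fit$model$lagged[2, ]), unname(coef(ref)[-1]),
               tolerance = 1e-10)
  expect_equal(unname(fit$coef_se[2, ]),
               unname(sqrt(diag(vcov(ref)))[-1]), tolerance = 1e-10)
})

test_that("mixed intervals make the pooled DT fit a blend across intervals", {
  # two sharply different intervals alternate, so the lagged curve is
  # sampled at two points where it takes very different values
  m <- ct_model(matrix(c(-1, 1.5, 0, -1), 2, 2), diffusion = diag(2))
  gaps <- rep(c(0.3, 3), 1500)
  y <- sample_ou_path(m, c(0, cumsum(gaps)), seed = 12)
  fit <- fit_dt_var(y)
  short <- lagged_params(m, 0.3)[2, 1]   # 0.333
  long <- lagged_params(m, 3)[2, 1]      # 0.224
  est <- fit$model$lagged[2, 1]
  # pooled estimate falls near the blended range, far below Phi(median dt)
  implied <- lagged_params(m, fit$model$interval)[2, 1]
  expect_gt(implied - est, 0.05)
  expect_lt(est, max(short, long) + 0.05)
})

test_that("uncertainty propagation is seeded and degenerates correctly", {
  A <- random_stable_drift(2, seed = 31, spectral_margin = 0.4, scale = 0.3)
  m <- ct_model(A, diffusion = diag(2))
  y <- sample_ou_path(m, seq(0, 599), seed = 13)
  fit <- fit_ct_var(y, n_starts = 1, seed = 14)
  fun <- function(mod) total_effect(mod, 1, 2, c(0.5, 1, 2))

  b1 <- propagate_uncertainty(fit, fun, n_draws = 200, seed = 15)
  b2 <- propagate_uncertainty(fit, fun, n_draws = 200, seed = 15)
  expect_identical(b1, b2)
  expect_true(all(b1$lower <= b1$est & b1$est <= b1$upper))

  # zero vcov: bands collapse onto the point estimate
  fit0 <- fit
  fit0$vcov <- matrix(0, length(fit$par), length(fit$par))
  b0 <- propagate_uncertainty(fit0, fun, n_draws = 50, seed = 16)
  expect_equal(b0$lower, b0$est, tolerance = 1e-12)
  expect_equal(b0$upper, b0$est, tolerance = 1e-12)
})

test_that("likelihood-based bands cover the true drift entry", {
  A <- random_stable_drift(2, seed = 41, spectral_margin = 0.4, scale = 0.3)
  m <- ct_model(A, diffusion = diag(2))
  hits <- 0L
  n_rep <- 10L
  for (r in seq_len(n_rep)) {
    y <- sample_ou_path(m, esm_schedule(100, 6, 13.5, seed = 500 + r),
                        seed = 600 + r)
    fit <- fit_ct_var(y, n_starts = 1, seed = r)
    b <- propagate_uncertainty(fit, function(mod) mod$drift[2, 1],
                               n_draws = 400, seed = 700 + r)
    if (b$lower <= A[2, 1] && A[2, 1] <= b$upper) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})
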