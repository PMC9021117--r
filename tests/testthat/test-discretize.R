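test_that("lagged_params reduces to scalar exponentials and the identity", {
  m <- ct_model(diag(c(-1, -2)))
  expect_equal(lagged_params(m, 1), diag(c(exp(-1), exp(-2))),
               ignore_attr = TRUE)
  expect_equal(lagged_params(m, 0), diag(2), ignore_attr = TRUE)
  expect_error(lagged_params(m, NA), "finite")
})

test_that("halving the interval and squaring recovers the lagged matrix", {
  for (seed in 1:10) {
    m <- random_ct_model(2 + seed %% 4, seed = seed)
    P1 <- lagged_params(m, 1)
    Ph <- lagged_params(m, 0.5)
    expect_lt(max(abs(Ph %*% Ph - P1)), 1e-10)
  }
})

test_that("lagged matrices satisfy the semigroup property", {
  for (seed in 1:10) {
    m <- random_ct_model(3, seed = seed)
    s <- runif(1, 0, 5); t <- runif(1, 0, 5)
    expect_lt(max(abs(lagged_params(m, s + t) -
                        lagged_params(m, s) %*% lagged_params(m, t))), 1e-10)
  }
})

test_that("stationary_cov solves the Lyapunov equation", {
  # closed form: A = -I, Q = 2I  =>  Gamma = I
  m <- ct_model(-diag(2), diffusion = 2 * diag(2))
  expect_equal(stationary_cov(m), diag(2), ignore_attr = TRUE)

  for (seed in 1:5) {
    m <- random_ct_model(3, seed = seed)
    G <- stationary_cov(m)
    expect_lt(max(abs(m$drift %*% G + G %*% t(m$drift) + m$diffusion)), 1e-9)
  }
  expect_error(stationary_cov(ct_model(matrix(0.1))), "stable")
})

test_that("residual_cov matches the scalar OU closed form and its limits", {
  m <- ct_model(matrix(-1), diffusion = matrix(2))
  expect_equal(residual_cov(m, 1)[1, 1], 1 - exp(-2), tolerance = 1e-10)
  expect_equal(residual_cov(m, 0)[1, 1], 0)
  expect_equal(residual_cov(m, 50)[1, 1], 1, tolerance = 1e-10)
})

test_that("residual_cov is PSD and Loewner-increasing in the interval", {
  for (seed in 1:5) {
    m <- random_ct_model(4, seed = seed)
    G <- stationary_cov(m)
    prev <- matrix(0, 4, 4)
    for (d in seq(0.2, 3, by = 0.2)) {
      S <- residual_cov(m, d)
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), -1e-10)
      dev <- eigen(S - prev, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(dev), -1e-9)
      prev <- S
    }
    # saturation at the stationary covariance
    expect_lt(max(abs(residual_cov(m, 200) - G)), 1e-8)
  }
})

test_that("dt_to_ct inverts the discretization", {
  # scalar: drift is log(phi) / interval
  ctm <- dt_to_ct(dt_model(matrix(0.5), interval = 1))
  expect_equal(ctm$drift[1, 1], log(0.5), tolerance = 1e-12)

  # round trip for drift matrices with real eigenvalues
  for (seed in 1:5) {
    set.seed(seed)
    P <- matrix(rnorm(9), 3, 3)
    A <- P %*% diag(-runif(3, 0.2, 2)) %*% solve(P)
    Phi <- lagged_params(ct_model(A), 0.7)
    rec <- dt_to_ct(dt_model(Phi, interval = 0.7))
    expect_lt(max(abs(rec$drift - A)), 1e-8)
  }

  # negative auto-regression has no real CT counterpart
  expect_error(dt_to_ct(dt_model(matrix(-0.3))), "logarithm")
})

test_that("dt_to_ct recovers the diffusion implied by the residual covariance", {
  m <- random_ct_model(3, seed = 7)
  d <- 0.8
  dtm <- dt_model(lagged_params(m, d), interval = d,
                  residual_cov = residual_cov(m, d))
  rec <- suppressWarnings(dt_to_ct(dtm))
  expect_lt(max(abs(rec$drift - m$drift)), 1e-7)
  expect_lt(max(abs(rec$diffusion - m$diffusion)), 1e-6)
})

test_that("phi_curve starts at identity, decays to zero, and locates peaks", {
  m <- ct_model(matrix(c(-1, 1.5, 0, -1), 2, 2))  # chain via a21 = 1.5
  pc0 <- phi_curve(m, 0)
  expect_equal(pc0$matrices[, , 1], diag(2), ignore_attr = TRUE)

  pc <- phi_curve(m, seq(0, 3, by = 0.01))
  # Jordan-block closed form: entry (2,1) = 1.5 * dt * exp(-dt), peak at dt = 1
  expect_equal(pc$matrices[2, 1, ],  1.5 * pc$grid * exp(-pc$grid),
               tolerance = 1e-9)
  expect_equal(pc$peak_dt[2, 1], 1, tolerance = 0.011)

  # large interval: all entries vanish
  expect_lt(max(abs(lagged_params(m, 50))), 1e-6)
  expect_error(phi_curve(m, numeric(0)), "empty")
})

test_that("the product-limit approximation converges to the matrix exponential", {
  m <- random_ct_model(4, seed = 3)
  E <- lagged_params(m, 1)
  approx_err <- vapply(c(1e2, 1e3, 1e4), function(n) {
    P <- diag(4) + m$drift / n
    nn <- n
    R <- diag(4)
    while (nn > 0) {  # binary exponentiation
      if (nn %% 2 == 1) R <- R %*% P
      P <- P %*% P
      nn <- nn %/% 2
    }
    max(abs(R - E))
  }, numeric(1))
  expect_true(all(diff(approx_err) < 0))
  expect_lt(approx_err[3], 1e-3)
})

test_that("sign_switch_report finds exactly the crossings that exist", {
  # diagonal drift: entries are positive exponentials, no switches
  expect_identical(nrow(sign_switch_report(
    phi_curve(ct_model(diag(c(-1, -2))), seq(0, 5, 0.1)))), 0L)

  # 2-variable chain: entry (2,1) = 1.5 dt e^{-dt} >= 0, never switches
  m <- ct_model(matrix(c(-1, 1.5, 0, -1), 2, 2))
  expect_identical(nrow(sign_switch_report(phi_curve(m, seq(0, 5, 0.1)))), 0L)

  # negative direct + positive indirect path: one switch for that entry
  A <- matrix(c(-1, 0, 0,
                 2, -1, 0,
                -0.5, 1, -1), 3, 3, byrow = TRUE)
  m3 <- ct_model(A)
  rep3 <- sign_switch_report(phi_curve(m3, seq(0, 5, 0.05)))
  hit <- rep3[rep3$from == "Y1" & rep3$to == "Y3", ]
  expect_identical(nrow(hit), 1L)
  # bracket refined to width 1e-4 and actually brackets a sign change
  expect_lt(hit$dt_upper - hit$dt_lower, 1.0001e-4)
  lo <- lagged_params(m3, hit$dt_lower)[3, 1]
  hi <- lagged_params(m3, hit$dt_upper)[3, 1]
  expect_lt(lo * hi, 0)
})
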