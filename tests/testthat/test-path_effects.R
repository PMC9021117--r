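test_that("total effects match closed forms and vanish at dt = 0", {
  m <- ct_model(matrix(c(-1, 0.8, 0, -1), 2, 2))
  expect_equal(total_effect(m, 1, 2, 0), 0)
  # Jordan-block closed form c * dt * exp(-dt)
  dts <- c(0.1, 0.5, 1, 2)
  expect_equal(total_effect(m, 1, 2, dts), 0.8 * dts * exp(-dts),
               tolerance = 1e-10)
  expect_error(total_effect(m, 1, 5, 1), "indices")
})

test_that("total effect equals the pulse-trajectory component", {
  for (seed in 1:5) {
    m <- random_ct_model(4, seed = seed)
    tr <- pulse_trajectory(m, intervention("pulse", 1, 1), c(0, 0.8))
    expect_equal(total_effect(m, 1, 3, 0.8), unname(tr$states[2, 3]),
                 tolerance = 1e-12)
  }
})

test_that("blocked_drift severs mediator rows and columns, keeps the diagonal", {
  ms <- example_models()$stress_discomfort_partial
  # no mediators: drift unchanged
  expect_equal(blocked_drift(ms, character(0))$modified_drift, ms$drift)

  b <- blocked_drift(ms, c("Stress", "SelfCon"))
  AD <- b$modified_drift
  # the classic blocked entries for Anxiety -> Discomfort via these mediators
  expect_identical(AD["Stress", "Anxiety"], 0)      # a12
  expect_identical(AD["SelfCon", "Anxiety"], 0)     # a32
  expect_identical(AD["Discomfort", "SelfCon"], 0)  # a43
  expect_equal(diag(AD), diag(ms$drift))
  # every off-diagonal entry in blocked rows/cols is zero
  M <- match(c("Stress", "SelfCon"), ms$labels)
  off <- AD
  diag(off) <- 0
  expect_true(all(off[M, ] == 0) && all(off[, M] == 0))

  # idempotence
  b2 <- blocked_drift(ct_model(AD, ms$diffusion), c("Stress", "SelfCon"))
  expect_equal(b2$modified_drift, AD)
  expect_error(blocked_drift(ms, "NotAVariable"), "unknown")
})

test_that("direct effects obey blocking semantics", {
  chain <- example_models()$chain3
  # blocking the only mediator kills the 1 -> 3 effect entirely
  for (d in c(0.2, 1, 3))
    expect_equal(direct_effect(chain, "Y1", "Y3", "Y2", d), 0)

  # empty mediator set: direct == total exactly
  m <- random_ct_model(4, seed = 2)
  expect_identical(direct_effect(m, 1, 3, integer(0), 1.2),
                   total_effect(m, 1, 3, 1.2))
  expect_error(direct_effect(m, 1, 3, c(1, 2), 1), "cause")
})

test_that("direct effects agree with the clamped ODE oracle", {
  for (seed in 1:5) {
    m <- random_ct_model(4, seed = 10 + seed)
    y0 <- rep(0, 4); y0[1] <- 1
    ode <- rk4_trajectory(m$drift, y0, 1, clamp = 2, n_steps = 2000)
    expect_equal(direct_effect(m, 1, 3, 2, 1), ode[3], tolerance = 1e-6)
    expect_equal(direct_effect(m, 1, 4, 2, 1), ode[4], tolerance = 1e-6)
  }
})

test_that("indirect = total - direct, exactly and structurally", {
  m <- random_ct_model(4, seed = 5)
  for (d in c(0, 0.3, 1, 2.5)) {
    te <- total_effect(m, 1, 4, d)
    de <- direct_effect(m, 1, 4, c(2, 3), d)
    expect_identical(indirect_effect(m, 1, 4, c(2, 3), d), te - de)
  }
  expect_equal(indirect_effect(m, 1, 4, c(2, 3), 0), 0)
  expect_error(indirect_effect(m, 1, 4, integer(0), 1), "empty")

  # pure chain: DE = 0 so IE == TE through the middle node
  chain <- example_models()$chain3
  dts <- seq(0.2, 3, by = 0.4)
  expect_equal(indirect_effect(chain, "Y1", "Y3", "Y2", dts),
               total_effect(chain, "Y1", "Y3", dts))
})

test_that("effect curves evaluate the scalar operations on a grid", {
  m <- random_ct_model(3, seed = 4, margin = 0.5)
  grid <- seq(0, 15, by = 0.25)
  tot <- effect_curve(m, "total", 1, 3, grid = grid)
  dir <- effect_curve(m, "direct", 1, 3, mediators = 2, grid = grid)
  ind <- effect_curve(m, "indirect", 1, 3, mediators = 2, grid = grid)
  expect_identical(ind$values, tot$values - dir$values)
  expect_identical(ind$values[1], 0)
  # all effects die out at long intervals for a stable model
  last <- length(grid)
  expect_lt(max(abs(c(tot$values[last], dir$values[last], ind$values[last]))),
            1e-2 * max(abs(tot$values)))
  df <- as.data.frame(ind)
  expect_identical(names(df),
                   c("dt", "kind", "cause", "effect", "mediators", "value"))
  expect_error(effect_curve(m, "indirect", 1, 3, grid = grid), "empty")
})

test_that("the path-tracing product limit converges to the closed forms", {
  m <- random_ct_model(4, seed = 9)
  te <- total_effect(m, 1, 3, 1)
  err4 <- abs(path_trace_oracle(m, "total", 1, 3, dt = 1, n_steps = 1e4) - te)
  err5 <- abs(path_trace_oracle(m, "total", 1, 3, dt = 1, n_steps = 1e5) - te)
  expect_lt(err4, 1e-3)
  expect_lt(err5, err4)

  de <- direct_effect(m, 1, 3, 2, 1)
  expect_equal(path_trace_oracle(m, "direct", 1, 3, 2, dt = 1, n_steps = 1e5),
               de, tolerance = 1e-4)

  # a structurally blocked path is zero at every resolution
  chain <- example_models()$chain3
  for (n in c(10, 1000))
    expect_identical(
      path_trace_oracle(chain, "direct", 1, 3, 2, dt = 1, n_steps = n), 0)
})
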