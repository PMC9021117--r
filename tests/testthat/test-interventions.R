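test_that("pulse trajectories solve the homogeneous dynamics", {
  # scalar: do(Y = 1) decays as exp(-t)
  m1 <- ct_model(matrix(-1))
  tr <- pulse_trajectory(m1, intervention("pulse", 1, 1), seq(0, 5, 0.5))
  expect_equal(unname(tr$states[, 1]), exp(-seq(0, 5, 0.5)), tolerance = 1e-10)

  m <- random_ct_model(4, seed = 1, margin = 0.5)
  spec <- intervention("pulse", c(1, 3), c(1, -0.5))
  tr4 <- pulse_trajectory(m, spec, c(0, 1, 40))
  # time 0: the do-assignment itself
  expect_equal(unname(tr4$states[1, ]), c(1, 0, -0.5, 0))
  # large t: back to equilibrium
  expect_lt(max(abs(tr4$states[3, ])), 1e-5)
  # against the ODE oracle
  ode <- rk4_trajectory(m$drift, c(1, 0, -0.5, 0), 1, n_steps = 2000)
  expect_equal(unname(tr4$states[2, ]), ode, tolerance = 1e-7)
  expect_warning(
    pulse_trajectory(ct_model(matrix(0.1)), intervention("pulse", 1, 1),
                     c(0, 1)),
    "not stable")
})

test_that("pulse responses are linear and superpose", {
  m <- random_ct_model(3, seed = 2)
  g <- seq(0, 2, 0.2)
  t1 <- pulse_trajectory(m, intervention("pulse", 1, 1), g)
  t2 <- pulse_trajectory(m, intervention("pulse", 1, 2), g)
  expect_equal(t2$states, 2 * t1$states, tolerance = 1e-12)

  tb <- pulse_trajectory(m, intervention("pulse", 2, 1), g)
  tboth <- pulse_trajectory(m, intervention("pulse", c(1, 2), c(1, 1)), g)
  expect_equal(tboth$states, t1$states + tb$states, tolerance = 1e-12)
})

test_that("press equilibrium and trajectory are mutually consistent", {
  # 2-variable closed form: 0 = -y1 + 0.5 * 1
  m <- ct_model(matrix(c(-1, 0, 0.5, -1), 2, 2))
  eq <- press_equilibrium(m, 2, 1)
  expect_equal(unname(eq), c(0.5, 1))
  # pressing at the equilibrium value changes nothing
  expect_equal(unname(press_equilibrium(m, 2, 0)), c(0, 0))

  m4 <- random_ct_model(4, seed = 3)
  spec <- intervention("press", 2, 1.5)
  g <- c(0, 0.5, 2, 60)
  tr <- press_trajectory(m4, spec, g)
  # pressed component constant at its value
  expect_true(all(tr$states[, 2] == 1.5))
  eq4 <- press_equilibrium(m4, 2, 1.5)
  expect_equal(unname(tr$states[4, ]), unname(eq4), tolerance = 1e-8)
  # clamped ODE oracle: pressed component held fixed
  ode <- rk4_trajectory(m4$drift, c(0, 1.5, 0, 0), 2, clamp = 2,
                        n_steps = 4000)
  expect_equal(unname(tr$states[3, ]), ode, tolerance = 1e-6)

  # press from equilibrium at value zero: nothing moves
  tr0 <- press_trajectory(m4, intervention("press", 2, 0), c(0, 1, 5))
  expect_lt(max(abs(tr0$states)), 1e-14)
})

test_that("a finite-duration press releases back to the old equilibrium", {
  m <- random_ct_model(3, seed = 4)
  spec <- intervention("press", 1, 1, duration = 2)
  tr <- press_trajectory(m, spec, c(0, 1, 2, 2.5, 80))
  expect_equal(tr$states[1:3, 1], rep(1, 3))   # held during the press
  expect_true(abs(tr$states[4, 1]) < 1)        # released and relaxing
  expect_lt(max(abs(tr$states[5, ])), 1e-6)    # old equilibrium restored
})

test_that("press stability is the stability of the free subsystem", {
  m <- ct_model(diag(c(-1, -2, -3)))
  expect_true(press_stability(m, 2)$stable)

  # stable overall (trace -0.5, det 1.5) but unstable once Y2 is pressed
  A <- matrix(c(0.5, -2, 1, -1), 2, 2, byrow = TRUE)
  m2 <- ct_model(A)
  expect_true(is_stable(m2))
  ps <- press_stability(m2, 2)
  expect_false(ps$stable)
  expect_equal(Re(ps$eigenvalues), 0.5)

  expect_error(press_stability(m, integer(0)), "empty")
  expect_error(press_stability(m, 1:3), "free subsystem")
})

test_that("clamped trajectories realize direct effects", {
  m <- random_ct_model(4, seed = 5)
  g <- c(0, 0.4, 1)
  # no clamping: identical to a pulse trajectory
  pl <- pulse_trajectory(m, intervention("pulse", 1, 1), g)
  cl0 <- clamped_trajectory(m, 1, 1, integer(0), g)
  expect_equal(cl0$states, pl$states)

  cl <- clamped_trajectory(m, 1, 1, 2, g)
  expect_true(all(cl$states[, 2] == 0))
  for (j in c(3, 4))
    expect_equal(unname(cl$states[3, j]), direct_effect(m, 1, j, 2, 1),
                 tolerance = 1e-12)

  # chain with the middle clamped: downstream never moves
  chain <- example_models()$chain3
  clc <- clamped_trajectory(chain, "Y1", 1, "Y2", seq(0, 4, 0.5))
  expect_true(all(clc$states[, 3] == 0))
  expect_error(clamped_trajectory(m, 1, 1, 1, g), "disjoint")
})
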