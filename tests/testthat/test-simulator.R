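test_that("stable_dt combines the advective, interaction and cap bounds", {
  cfg <- run_config(t_end = 1, dt_max = 1, safety = 0.5)
  m <- make_model(M = 10, iota = 1, pi_rate = 0, force = 0)
  f <- matrix(0.5, 1, 10) # mu = 1
  expect_equal(stable_dt(f, m, cfg), 0.5)

  # all dynamics off: the cap is the only bound
  m0 <- make_model(M = 10, iota = 0, force = 0)
  expect_equal(stable_dt(f, m0, cfg), 1)

  # doubling the mass halves the interaction bound
  expect_equal(stable_dt(2 * f, m, cfg), 0.25)

  # advective bound: cfl * du / max |a|
  mf <- make_model(M = 10, iota = 0, force = 2)
  cfg2 <- run_config(t_end = 1, dt_max = 1, cfl = 0.8)
  expect_equal(stable_dt(f, mf, cfg2), 0.8 * 0.2 / 2)
})

test_that("rk4 leaves equilibria alone and has fifth-order local error", {
  m <- make_model(M = 10)
  z <- matrix(0, 1, 10)
  expect_equal(step_rk4(z, m, 0.1), z)

  # uniform destructive regime: profile stays uniform, mass obeys
  # dmu/dt = -mu^2, so mu(dt) = 1/(1 + dt) exactly
  md <- make_model(M = 10, iota = 1, pi_rate = -1)
  f <- matrix(0.5, 1, 10)
  err_dt <- sapply(c(0.1, 0.05), function(dt) {
    f1 <- step_rk4(f, md, dt)
    abs(sum(f1) * md$grid$du - 1 / (1 + dt))
  })
  expect_lt(err_dt[1], 1e-5)
  # halving dt shrinks the one-step error ~ 2^5
  expect_gt(err_dt[1] / err_dt[2], 20)
  expect_lt(err_dt[1] / err_dt[2], 45)
})

test_that("step doubling on the thermostated fixture is fifth-order small", {
  th <- ktap_scenario("thermostated", M = 50)
  err <- sapply(c(0.02, 0.01), function(dt) {
    f1 <- step_rk4(th$f0, th$model, dt)
    f2 <- step_rk4(step_rk4(th$f0, th$model, dt / 2), th$model, dt / 2)
    max(abs(f1 - f2))
  })
  expect_lt(err[1], 1e-4)
  expect_gt(err[1] / err[2], 20)
  expect_lt(err[1] / err[2], 45)
})

test_that("conservative runs conserve mass to accumulated roundoff", {
  sc <- ktap_scenario("conservative-uniform", M = 100)
  r <- run_kinetic(sc$model, sc$f0, run_config(t_end = 5))
  expect_identical(r$status, "completed")
  m <- r$moments
  expect_lt(abs(m$mu[nrow(m)] - m$mu[1]), 1e-10)
  expect_gte(r$min_f_observed, 0)
})

test_that("quadratic proliferation follows the closed-form blow-up law", {
  pr <- ktap_scenario("proliferative", M = 50)
  r <- run_kinetic(pr$model, pr$f0,
                   run_config(t_end = 1, dt_max = 0.05, record_every = 1))
  m <- r$moments
  expect_equal(m$mu, 1 / (1 - 0.5 * m$time), tolerance = 1e-3)
  expect_equal(m$mu[nrow(m)], 2, tolerance = 1e-3)

  rb <- run_kinetic(pr$model, pr$f0, run_config(t_end = 10))
  expect_identical(rb$status, "blowup_detected")
  expect_lt(abs(rb$blowup_time_estimate - 2) / 2, 0.02)
})

test_that("moment series is recorded at the configured cadence", {
  sc <- ktap_scenario("conservative-uniform", M = 20)
  r <- run_kinetic(sc$model, sc$f0,
                   run_config(t_end = 1, dt_max = 0.1, record_every = 5))
  # 10 equal steps of dt_max: initial record plus one every 5 steps
  expect_identical(r$n_steps, 10L)
  expect_identical(nrow(r$moments), 3L)
  expect_equal(r$moments$time, c(0, 0.5, 1), tolerance = 1e-12)
})

test_that("steady states: equilibria converge, growing masses do not", {
  sc <- ktap_scenario("conservative-uniform", M = 30)
  ss <- steady_state(sc$model, sc$f0, tol = 1e-8, t_cap = 1)
  expect_true(ss$converged)
  expect_equal(ss$time, 0) # already at the interaction equilibrium

  z <- matrix(0, 1, 30)
  ssz <- steady_state(sc$model, z, tol = 1e-10, t_cap = 1)
  expect_true(ssz$converged)

  pr <- ktap_scenario("proliferative", M = 30)
  ssp <- steady_state(pr$model, pr$f0, tol = 1e-8, t_cap = 30)
  expect_false(ssp$converged)
})

test_that("run result methods expose the moment series", {
  sc <- ktap_scenario("conservative-uniform", M = 20)
  r <- run_kinetic(sc$model, sc$f0, run_config(t_end = 0.5))
  df <- as.data.frame(r)
  expect_true(all(c("time", "mu", "mu_bar", "E_1_1") %in% names(df)))
  expect_output(print(r), "completed")
  expect_output(summary(r), "mass mu")
})
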