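test_that("E1 right-hand side matches hand-evaluated cases", {
  p1 <- riccati_params(F = 1, iota = 0, pi_rate = 0, mu = 1, mu_bar = 1)
  expect_equal(riccati_rhs_E1(1, 0, p1), 0)

  p2 <- riccati_params(F = 0, iota = 1, pi_rate = 0, mu = 1, mu_bar = 1)
  expect_equal(riccati_rhs_E1(1, 0, p2), -1)

  p3 <- riccati_params(F = 1, iota = 1, pi_rate = 0, mu = 1, mu_bar = 2)
  expect_equal(riccati_rhs_E1(1, 0, p3), 0)
})

test_that("constant root matches hand evaluations and zeroes the rhs", {
  expect_equal(riccati_fixed_point(1, 0, 0, 1, 1), 1)
  expect_equal(riccati_fixed_point(1, 1, 0, 1, 2), 1) # (3 - 1) / 2
  expect_equal(riccati_fixed_point(2, 1, 0, 1, 0), 0)
  expect_error(riccati_fixed_point(0, 1, 0, 1, 1), class = "division-error")
  expect_error(riccati_fixed_point(1, 1, 0, 1, -5), class = "domain-error")
})

test_that("fixed point zeroes the rhs across a seeded parameter sweep", {
  set.seed(11)
  for (rep in 1:100) {
    F <- runif(1, 0.1, 5); cc <- runif(1, 0, 5); mb <- runif(1, 0, 5)
    Ebar <- riccati_fixed_point(F, cc, 0, 1, mb)
    p <- riccati_params(F = F, iota = cc, pi_rate = 0, mu = 1, mu_bar = mb)
    expect_lt(abs(riccati_rhs_E1(Ebar, 0, p)), 1e-12)
  }
})

test_that("closed form honors the initial condition and fixed point exactly", {
  p <- riccati_params(F = 1, iota = 1, pi_rate = 0, mu = 1, mu_bar = 2)
  expect_identical(riccati_closed_form(0, 0.3, p), 0.3)
  Ebar <- riccati_fixed_point(1, 1, 0, 1, 2)
  expect_equal(riccati_closed_form(c(0, 1, 7), Ebar, p), rep(Ebar, 3))
  # convergence to the constant root
  expect_equal(riccati_closed_form(60, 0, p), Ebar, tolerance = 1e-12)
})

test_that("closed form agrees with the adaptive solver, including c = 0", {
  tt <- seq(0, 3, by = 0.05)
  p <- riccati_params(F = 1, iota = 0, pi_rate = 0, mu = 1, mu_bar = 1)
  expect_lt(max(abs(riccati_closed_form(tt, 0, p) -
                      solve_moment_ode_E1(0, tt, p))), 1e-6)
})

test_that("closed form refuses time-dependent coefficients and F = 0", {
  pt <- riccati_params(F = 1, iota = 1, pi_rate = 0,
                       mu = function(t) 1 + t, mu_bar = 1)
  expect_error(riccati_closed_form(1, 0, pt), class = "unsupported-regime")
  p0 <- riccati_params(F = 0, iota = 1, pi_rate = 0, mu = 1, mu_bar = 1)
  expect_error(riccati_closed_form(1, 0, p0), class = "division-error")
})

test_that("trajectories below the negative root raise at the escape time", {
  # dE/dt = 1 - E^2 from E(0) = -2 escapes at t = atanh(1/2) = log(3)/2
  p <- riccati_params(F = 1, iota = 0, pi_rate = 0, mu = 1, mu_bar = 1)
  err <- tryCatch(riccati_closed_form(c(0, 1), -2, p), error = identity)
  expect_s3_class(err, "singularity")
  expect_match(conditionMessage(err), format(round(log(3) / 2, 3)),
               fixed = TRUE)
  # just before the escape the closed form is still finite and accurate
  tt <- seq(0, 0.5, by = 0.05)
  expect_lt(max(abs(riccati_closed_form(tt, -2, p) -
                      solve_moment_ode_E1(-2, tt, p))), 1e-5)
})

test_that("field-free regime decays exponentially at rate iota mu", {
  p <- riccati_params(F = 0, iota = 1, pi_rate = 0, mu = 1, mu_bar = 1)
  expect_equal(solve_moment_ode_E1(1, c(0, 1), p)[2], exp(-1),
               tolerance = 1e-6)
  # pi = 1 freezes the moment entirely
  p1 <- riccati_params(F = 0, iota = 1, pi_rate = 1, mu = 1, mu_bar = 1)
  expect_equal(solve_moment_ode_E1(0.4, c(0, 2, 5), p1), rep(0.4, 3),
               tolerance = 1e-10)
})

test_that("(p, q) moment equation honors both sign conventions", {
  base <- function(mode) riccati_params(F = 0, iota = 1, pi_rate = 0,
                                        mu = 1, mu_bar = 1, p = 1, q = 1,
                                        sign_mode = mode)
  expect_equal(solve_moment_ode_pq(1, c(0, 1), base("as_printed"))[2],
               exp(1), tolerance = 1e-6)
  expect_equal(solve_moment_ode_pq(1, c(0, 1),
                                   base("theorem4_consistent"))[2],
               exp(-1), tolerance = 1e-6)
  # pi = 1 with F = 0: constant under both conventions
  for (mode in c("as_printed", "theorem4_consistent")) {
    pz <- riccati_params(F = 0, iota = 1, pi_rate = 1, mu = 1, mu_bar = 1,
                         sign_mode = mode)
    expect_equal(solve_moment_ode_pq(2, c(0, 1, 3), pz), rep(2, 3),
                 tolerance = 1e-10)
  }
})

test_that("driven (p, q) equation demands the lower moment", {
  p <- riccati_params(F = 1, iota = 1, pi_rate = 0, mu = 1, mu_bar = 1,
                      p = 1, q = 1)
  expect_error(solve_moment_ode_pq(1, c(0, 1), p),
               class = "missing-dependency")
  p2 <- riccati_params(F = 1, iota = 1, pi_rate = 0, mu = 1, mu_bar = 1,
                       mu_tilde = 1, p = 1, q = 1)
  tr <- solve_moment_ode_pq(0, c(0, 0.5, 1), p2,
                            E_lower_fn = function(t) rep(1, length(t)))
  expect_true(all(is.finite(tr)))
})
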