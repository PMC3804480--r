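# Hand-derived operator values on the canonical fixtures, plus the
# structural identities (quadratic homogeneity, exact conservative
# cancellation, the mass-production identity) and the dual gain routes.

test_that("uniform interaction equilibrium: gain = loss = 0.5 pointwise", {
  sc <- ktap_scenario("conservative-uniform", M = 40)
  G <- gain_term(sc$f0, sc$model)
  L <- loss_term(sc$f0, sc$model)
  expect_equal(as.vector(G), rep(0.5, 40), tolerance = 1e-14)
  expect_equal(as.vector(L), rep(0.5, 40), tolerance = 1e-14)
  expect_lt(max(abs(G - L)), 1e-14)
  expect_lt(max(abs(kinetic_rhs(sc$f0, sc$model))), 1e-14)
})

test_that("operators vanish on the zero state and for zero rates", {
  m <- make_model(M = 10)
  z <- matrix(0, 1, 10)
  expect_equal(gain_term(z, m), z)
  expect_equal(loss_term(z, m), z)
  m0 <- make_model(M = 10, iota = 0)
  f <- rand_state(m0)
  expect_equal(loss_term(f, m0), matrix(0, 1, 10))
  expect_equal(nonconservative_term(f, make_model(M = 10, pi_rate = 0)),
               matrix(0, 1, 10))
})

test_that("a silent velocity class contributes nothing to the gain", {
  m <- make_model(M = 10, v = c(1, 2))
  f <- rand_state(m)
  f2 <- f; f2[2, ] <- 0
  # with f_2 = 0 the i = 1 gain only sees the j = 1 encounter
  m1 <- make_model(M = 10, v = 1)
  expect_equal(gain_term(f2, m)[1, ],
               gain_term(f2[1, , drop = FALSE], m1)[1, ],
               tolerance = 1e-14)
  expect_equal(gain_term(f2, m)[2, ], rep(0, 10))
})

test_that("nonconservative values match hand arithmetic on uniform profiles", {
  pr <- ktap_scenario("proliferative", M = 40)
  N <- nonconservative_term(pr$f0, pr$model)
  expect_equal(as.vector(N), rep(0.25, 40), tolerance = 1e-14)

  destr <- make_model(M = 40, pi_rate = -0.2)
  f <- matrix(0.5, 1, 40)
  expect_equal(as.vector(nonconservative_term(f, destr)), rep(-0.1, 40),
               tolerance = 1e-14)
})

test_that("thermostat term matches the pointwise product formula", {
  m <- make_model(M = 10, force = 1, thermostat = TRUE)
  f <- initial_state(m, function(u) (1 + u) / 2)
  Tm <- thermostat_term(f, m, E1 = 1 / 3)
  # centers of [-1,1] with M = 10 put u = 0.5 in cell 8
  expect_equal(Tm[1, 8], 0.5 * 1 * 0.75 * (1 / 3), tolerance = 1e-14)
  expect_equal(thermostat_term(f, m, E1 = 0), 0 * f)
  m0 <- make_model(M = 10, force = 0, thermostat = TRUE)
  expect_equal(thermostat_term(f, m0, E1 = 0.7), 0 * f)
})

test_that("transport of a constant profile with constant field is zero inside", {
  m <- make_model(M = 20, force = 1)
  f <- matrix(1, 1, 20)
  Tr <- transport_term(f, m, E1 = 0)
  expect_equal(Tr[1, 2:20], rep(0, 19))
  # the inflow cell sees the zero ghost state
  expect_equal(Tr[1, 1], -1 / m$grid$du)
})

test_that("upwind transport converges to the analytic derivative at order >= 0.9", {
  err <- sapply(c(100, 200), function(M) {
    m <- make_model(M = M, force = 1)
    u <- m$grid$centers
    f <- matrix(0.75 * (1 - u^2), 1, M)
    Tr <- transport_term(f, m, E1 = 0)
    exact <- 2 * 0.75 * u # -d/du f
    keep <- 6:(M - 5)
    max(abs(Tr[1, keep] - exact[keep]))
  })
  order <- log2(err[1] / err[2])
  expect_gte(order, 0.9)
})

test_that("transport mass change telescopes to the boundary flux", {
  m <- make_model(M = 30, force = 1, thermostat = TRUE)
  u <- m$grid$centers
  f0 <- pmax(0.25 - (u - 0.1)^2, 0) # vanishes in the outermost cells
  f <- matrix(f0, 1, 30)
  Tr <- transport_term(f, m, E1 = 0.4)
  expect_lt(abs(sum(Tr) * m$grid$du), 1e-12)
})

test_that("interaction operators are quadratically homogeneous in f", {
  m <- make_model(M = 12, v = c(1, -1), iota = function(u1, u2) 1 + u1^2,
                  pi_rate = function(u1, u2) 0.3 * u2, force = 1,
                  thermostat = TRUE)
  f <- rand_state(m, seed = 4)
  E1 <- moment_pq(f, m, 1, 1)
  for (s in c(0.5, 2)) {
    expect_equal(gain_term(s * f, m), s^2 * gain_term(f, m),
                 tolerance = 1e-12)
    expect_equal(loss_term(s * f, m), s^2 * loss_term(f, m),
                 tolerance = 1e-12)
    expect_equal(nonconservative_term(s * f, m),
                 s^2 * nonconservative_term(f, m), tolerance = 1e-12)
    expect_equal(thermostat_term(s * f, m, s * E1),
                 s^2 * thermostat_term(f, m, E1), tolerance = 1e-12)
  }
})

test_that("gain and loss masses cancel exactly per velocity class", {
  for (seed in 1:5) {
    m <- make_model(M = 15, v = c(0.5, 2),
                    iota = function(u1, u2) exp(-(u1 - u2)^2))
    f <- rand_state(m, seed = seed)
    G <- gain_term(f, m); L <- loss_term(f, m)
    du <- m$grid$du
    for (i in 1:2)
      expect_lt(abs(sum(G[i, ]) * du - sum(L[i, ]) * du), 1e-12)
  }
})

test_that("total nonconservative mass equals iota * pi * mu^2 for constants", {
  m <- make_model(M = 20, v = c(1, 3), iota = 0.7, pi_rate = -0.4)
  f <- rand_state(m, seed = 2)
  mu <- moment_pq(f, m, 0, 0)
  expect_equal(sum(nonconservative_term(f, m)) * m$grid$du,
               0.7 * (-0.4) * mu^2, tolerance = 1e-12)
})

test_that("separable and dense gain contraction routes agree", {
  g <- activity_grid(-1, 1, 12)
  tr <- transition_gaussian(g, center = 0.2, sigma = 0.4)
  dense <- ktap:::as_dense_transition(tr)
  iota_fn <- function(u1, u2) 1 + 0.5 * u1 * u2
  kern_s <- interaction_kernels(g, 1, iota = iota_fn, transition = tr)
  kern_d <- interaction_kernels(g, 1, iota = iota_fn, transition = dense)
  ms <- kinetic_model(g, velocity_set(1), kern_s)
  md <- kinetic_model(g, velocity_set(1), kern_d)
  f <- rand_state(ms, seed = 3)
  expect_equal(gain_term(f, ms), gain_term(f, md), tolerance = 1e-13)
})

test_that("shape mismatches raise dimension errors", {
  m <- make_model(M = 10)
  expect_error(gain_term(matrix(1, 1, 9), m), class = "dimension-mismatch")
  expect_error(loss_term(matrix(1, 2, 10), m), class = "dimension-mismatch")
})
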