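test_that("kernel validation passes for constructor-built densities", {
  sc <- ktap_scenario("conservative-uniform", M = 50)
  v <- validate_model(sc$model, n_samples = 10, seed = 7)
  expect_true(v$pass)
  expect_lte(v$max_norm_error, 1e-12)
  expect_gte(v$min_iota, 0)
  expect_gte(v$min_A, 0)
})

test_that("a mis-scaled transition density is flagged with error near one", {
  g <- activity_grid(-1, 1, 20)
  tr <- transition_uniform(g)
  tr$dens <- tr$dens * 2 # deliberately corrupted
  kern <- interaction_kernels(g, 1, iota = 1, transition = tr)
  model <- kinetic_model(g, velocity_set(1), kern)
  v <- validate_model(model)
  expect_false(v$pass)
  expect_equal(v$max_norm_error, 1, tolerance = 1e-12)
})

test_that("negative iota is rejected at construction", {
  g <- activity_grid(-1, 1, 10)
  expect_error(
    interaction_kernels(g, 1, iota = function(u1, u2) u1,
                        transition = transition_uniform(g)),
    class = "invalid-parameter")
})

test_that("scenario catalogue is deterministic and validates", {
  a <- ktap_scenario("conservative-uniform")
  b <- ktap_scenario("conservative-uniform")
  expect_identical(a$f0, b$f0)
  expect_identical(a$model$kernels$iota_mats, b$model$kernels$iota_mats)

  expect_equal(moment_pq(a$f0, a$model, 0, 0), 1)

  th <- ktap_scenario("thermostated")
  expect_lt(abs(moment_pq(th$f0, th$model, 1, 1)), 1e-14) # even profile
  expect_equal(moment_pq(th$f0, th$model, 0, 0), 1)

  pr <- ktap_scenario("proliferative")
  expect_true(pr$model$kernels$pi_const)
  expect_equal(pr$model$kernels$pi_value, 0.5)

  expect_error(ktap_scenario("not-a-scenario"), class = "unknown-scenario")
  expect_error(ktap_scenario("not-a-scenario"), "conservative-uniform")
})

test_that("mismatched components are rejected", {
  g <- activity_grid(-1, 1, 10)
  kern <- interaction_kernels(g, 2, iota = 1,
                              transition = transition_uniform(g))
  expect_error(kinetic_model(g, velocity_set(1), kern),
               class = "dimension-mismatch")
  g2 <- activity_grid(-1, 1, 12)
  kern2 <- interaction_kernels(g, 1, iota = 1,
                               transition = transition_uniform(g))
  expect_error(kinetic_model(g2, velocity_set(1), kern2),
               class = "dimension-mismatch")
})
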