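test_that("balancing identities certify the bundled triples", {
  for (fx in list(fixture_third_order(), fixture_coupled_lv())) {
    rep <- residual_identities(fx$system, fx$solution, fx$aux)
    expect_true(rep$pass)
    expect_named(rep$residuals,
                 c("x_const_l1", "x_linear_l1", "y_linear_l1", "y_const_l1",
                   "x_const_l2", "x_linear_l2", "y_linear_l2", "y_const_l2"))
    expect_true(ode_residual(fx$system, fx$solution)$pass)
  }
})

test_that("both oracles detect a perturbed coefficient", {
  fx <- fixture_coupled_lv()
  pert <- fx$system
  pert$lambda[2] <- pert$lambda[2] + bigq("1/1000000")
  expect_false(residual_identities(pert, fx$solution, fx$aux)$pass)
  rep <- ode_residual(pert, fx$solution)
  expect_false(rep$pass)
  # only the x-equation of subsystem 2 is affected
  expect_true(all(bq_is_zero(rep$residuals$x_l1)))
  expect_false(all(bq_is_zero(rep$residuals$x_l2)))
})

test_that("rate scaling: the quarter-rate system is not solved by the solution", {
  fx <- fixture_third_order()
  expect_false(ode_residual(fx$quarter_system, fx$solution)$pass)
  # scaling all 18 coefficients back up by 4 restores the exact solve
  scaled <- fx$quarter_system
  for (nm in names(scaled)) scaled[[nm]] <- bigq(4) * scaled[[nm]]
  expect_true(system_equal(scaled, fx$system))
  expect_true(ode_residual(scaled, fx$solution)$pass)
})

test_that("numerical integration agrees with the closed form", {
  fx <- fixture_coupled_lv()
  dev <- integrate_and_compare(fx$system, fx$solution, c(0, 10))
  expect_lt(dev, 1e-6)
  # pole inside the window is refused up front
  sol_pole <- lv_solution(2, eta = 1, t0 = 0, sigmas = c(1, 1, 1, 1),
                          aes = c("-6", "1"),
                          ratios = list(x1 = c("1", "1"), y1 = c("1", "1"),
                                        x2 = c("1", "1"), y2 = c("1", "1")))
  expect_error(integrate_and_compare(fx$system, sol_pole, c(0, 2)), "pole")
})

test_that("fixture generator is deterministic and leaves the RNG alone", {
  set.seed(99)
  before <- runif(1)
  f1 <- generate_fixture(2, seed = 7, ranges = list(max_abs = 6))
  after <- runif(1)
  set.seed(99)
  expect_identical(c(before, after), runif(2))
  f2 <- generate_fixture(2, seed = 7, ranges = list(max_abs = 6))
  expect_true(system_equal(f1$system, f2$system))
  expect_true(all(f1$eta == f2$eta) && all(f1$aes == f2$aes))
  # different seeds give different instances
  f3 <- generate_fixture(2, seed = 8, ranges = list(max_abs = 6))
  expect_false(system_equal(f1$system, f3$system))
})

test_that("generated fixtures are certified across orders", {
  for (n in 1:3) {
    fix <- generate_fixture(n, seed = 11, ranges = list(max_abs = 6))
    expect_s3_class(fix, "lv_fixture")
    expect_true(residual_identities(fix$system, fix$solution, fix$aux)$pass)
    expect_true(ode_residual(fix$system, fix$solution)$pass)
  }
  # above order three the generator zeroes exactly n - 3 coefficients
  fix4 <- generate_fixture(4, seed = 3, ranges = list(max_abs = 6))
  expect_identical(fix4$zero_aes, 2L)
  expect_true(bq_is_zero(fix4$aes[3]))
  expect_true(ode_residual(fix4$system, fix4$solution)$pass)
})
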