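test_that("decay rate of a scalar Riccati equation", {
  et <- riccati_eta(lv_riccati("-1", "5", "-4"))
  expect_true(et$real)
  expect_equal(as.character(et$eta), "3")
  expect_equal(et$eta_num, 3)
  neg <- riccati_eta(lv_riccati("1", "0", "1"))
  expect_false(neg$real)
  expect_true(is.na(neg$eta_num))
  # irrational rate: real but not exactly representable
  irr <- riccati_eta(lv_riccati("-1", "0", "2"))
  expect_true(irr$real)
  expect_true(is.na(unclass(irr$eta)))
  expect_error(lv_riccati("1", "1", "0"), "c2")
})

test_that("kink coefficients round-trip", {
  k <- lv_kink(sigma = "1", x0_root = "1/4", t0_root = "1", s = "-2",
               eta = "3")
  eq <- kink_coeffs(k)
  expect_equal(as.character(c(eq$c0, eq$c1, eq$c2)), c("-1", "5", "-4"))
  k2 <- kink_from_coeffs(eq, x_init = "1/2")$solution
  eq2 <- kink_coeffs(k2)
  expect_true(eq$c0 == eq2$c0 && eq$c1 == eq2$c1 && eq$c2 == eq2$c2)
  expect_error(lv_kink("1", "2", "2", "1", "1"), "differ")
})

test_that("kink construction from coefficients", {
  eq <- lv_riccati("-1", "5", "-4")
  kk <- kink_from_coeffs(eq, x_init = "1/2")
  sol <- kk$solution
  expect_equal(as.character(sol$sigma), "1")
  expect_equal(as.character(sol$x0_root), "1/4")
  expect_equal(as.character(sol$s), "-2")
  expect_true(kink_residual(sol, eq)$pass)
  # passes through the initial condition
  expect_equal(kink_evaluate(sol, 0), 0.5)
  # the two limits are the equilibria 1/4 and 1
  expect_equal(kink_evaluate(sol, c(-30, 30)), c(0.25, 1), tolerance = 1e-9)
  # residual detects a perturbed equation
  expect_false(kink_residual(sol, lv_riccati("-1", "5", "-5"))$pass)
  # starting at an equilibrium yields the constant solution (s = 0)
  at_eq <- kink_from_coeffs(eq, x_init = "1")
  expect_true(bq_is_zero(at_eq$solution$s))
  # irrational rate is refused in exact construction
  expect_error(kink_from_coeffs(lv_riccati("-1", "0", "2"), "0"),
               "irrational")
  # pole when s > 0 (initial value outside the equilibrium interval)
  out <- kink_from_coeffs(eq, x_init = "2")
  expect_false(is.na(out$pole_time))
})

test_that("pair existence conditions on the bundled instance", {
  sys <- fixture_pair()
  rep <- pair_existence_check(sys)
  expect_true(rep$pass)
  for (r in rep$residuals) expect_true(bq_is_zero(r))
  expect_equal(as.character(pair_eta(sys)), "1")
})

test_that("pair existence conditions reject and simplify as expected", {
  bad <- lv_pair(a = c("1", "1", "1", "1"), b = c("1", "1", "2", "1"))
  rep <- pair_existence_check(bad)
  expect_false(rep$pass)
  expect_false(bq_is_zero(rep$residuals$a3_minus_b2))
  # mirror-symmetric coefficients with a1 = b1 = 0: cubic residual vanishes
  sym <- lv_pair(a = c("2", "0", "3", "3"), b = c("2", "0", "3", "3"))
  expect_true(bq_is_zero(pair_existence_check(sym)$residuals$cubic_condition))
  # same shape with a1 = b1 = 1 nonzero: residual 2a1^3 - 18 a0 a2 a1
  sym1 <- lv_pair(a = c("2", "1", "3", "3"), b = c("2", "1", "3", "3"))
  expect_equal(as.character(pair_existence_check(sym1)$residuals$cubic_condition),
               as.character(bigq(2) - bigq(18) * bigq(2) * bigq(3)))
})

test_that("root-parameter constraints", {
  # (a, -a) with symmetric denominator roots (1, -1) satisfies the relation
  rep <- pair_root_constraints(c("3/2", "-3/2"), c("7", "-7"), c("1", "-1"))
  expect_true(rep$pass)
  rep2 <- pair_root_constraints(c("2", "5"), c("1", "3"), c("1", "-1"))
  expect_false(rep2$pass)
  expect_error(pair_root_constraints(c("1", "0"), c("1", "2"), c("1", "2")),
               "zero")
})

test_that("inverse-relationship detection", {
  # T = (x+2)(x+3); X = (x+2)^2, Y = (x+3)^2 so that X*Y = T^2
  x_comp <- lv_component("3", c("2/3", "4/5"), c("6", "5"))
  y_comp <- lv_component("1/3", c("3/2", "6/5"), c("6", "5"))
  chk <- inverse_relation_check(x_comp, y_comp)
  expect_true(chk$constant)
  expect_equal(as.character(chk$omega), "1")
  chk2 <- inverse_relation_check(x_comp, x_comp)
  expect_false(chk2$constant)
  expect_true(is.na(unclass(chk2$omega)))
})
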