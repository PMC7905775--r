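test_that("component stores coefficient-first representation", {
  cmp <- lv_component("4", c("30", "-25", "5"), c("1", "5", "15"))
  expect_equal(as.character(cmp$num$coef), c("30", "-125", "75", "1"))
  expect_equal(as.character(cmp$den$coef), c("1", "5", "15", "1"))
  expect_equal(cmp$order, 3L)
  expect_error(lv_component("1", c("1", "2"), c("1")), "equal length")
  expect_error(lv_component("1", c("1", "2"), c("0", "0")), "zero")
  expect_error(lv_component(c("1", "2"), "1", "1"), "single")
})

test_that("time transform", {
  expect_equal(transform_time(5, 1, 5), 1)
  expect_equal(transform_time(log(2), 4, 0), 16)
  expect_equal(transform_time(0, "-2", "1/2"), exp(1))
  expect_true(all(diff(transform_time(1:5, 3, 0)) > 0))
})

test_that("solution evaluation matches hand computation", {
  sol <- lv_solution(1, eta = 2, t0 = 0, sigmas = c("2", "3", "4", "5"),
                     aes = "3",
                     ratios = list(x1 = "1/3", y1 = "2", x2 = "-1",
                                   y2 = "1/2"))
  # at t = 0, that = 1: value = sigma * (1 + r*ae) / (1 + ae)
  v <- evaluate_solution(sol, 0)
  expect_equal(v$x1, 2 * (1 + 1) / 4)
  expect_equal(v$y1, 3 * (1 + 6) / 4)
  expect_equal(v$x2, 4 * (1 - 3) / 4)
  expect_equal(v$y2, 5 * (1 + 1.5) / 4)
  expect_error(lv_solution(1, 0, 0, c(1, 1, 1, 1), "1",
                           list(x1 = "1", y1 = "1", x2 = "1", y2 = "1")),
               "eta")
})

test_that("limits follow the rate's sign", {
  cmp <- lv_component("2", c("1/2", "3"), c("4", "1"))
  lim <- component_limits(cmp, eta = 1)
  expect_equal(unname(as.character(lim["t_minus_inf"])), "1")  # sigma * ratio0
  expect_equal(unname(as.character(lim["t_plus_inf"])), "2")
  swapped <- component_limits(cmp, eta = "-3")
  expect_equal(unname(as.character(swapped["t_minus_inf"])), "2")
  # indeterminate constant-term ratio when ae0 = 0
  cmp0 <- lv_component("2", c("1/2", "3"), c("0", "1"))
  expect_true(is.na(unclass(component_limits(cmp0, 1)["t_minus_inf"])))
})

test_that("roots are derived views of the coefficients", {
  cmp <- lv_component("1", c("2/1", "3"), c("1", "1"))  # num x^2+3x+2
  rts <- roots_from_coeffs(cmp)
  expect_equal(sort(as.numeric(rts$num_roots_exact)), c(-2, -1))
  expect_equal(sort(Re(rts$num_roots)), c(-2, -1), tolerance = 1e-9)
  # round-trip: coefficients -> exact roots -> coefficients
  expect_true(qp_equal(qp_from_roots(rts$num_roots_exact), cmp$num))
})

test_that("poles map back to real times only for positive real roots", {
  # denominator (that - 2)(that + 3): pole at that = 2 only
  sol <- lv_solution(2, eta = 1, t0 = 0, sigmas = c(1, 1, 1, 1),
                     aes = c("-6", "1"),
                     ratios = list(x1 = c("1", "1"), y1 = c("1", "1"),
                                   x2 = c("1", "1"), y2 = c("1", "1")))
  expect_equal(pole_times(sol), log(2))
  expect_error(evaluate_solution(sol, log(2)), "pole")
  expect_equal(nrow(evaluate_solution(sol, c(0, 1))), 2L)
  # complex denominator roots: no real pole
  sol2 <- lv_solution(2, eta = 1, t0 = 0, sigmas = c(1, 1, 1, 1),
                      aes = c("1", "1"),
                      ratios = list(x1 = c("1", "1"), y1 = c("1", "1"),
                                    x2 = c("1", "1"), y2 = c("1", "1")))
  expect_length(pole_times(sol2), 0L)
})
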