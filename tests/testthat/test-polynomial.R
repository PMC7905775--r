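test_that("polynomial arithmetic is exact", {
  p <- qpoly(c("1", "2", "1"))            # (x+1)^2
  q <- qpoly(c("-1", "1"))                # x - 1
  expect_equal(qp_degree(p), 2L)
  expect_equal(as.character(qp_mul(p, q)$coef), c("-1", "-1", "1", "1"))
  expect_equal(as.character(qp_add(p, q)$coef), c("0", "3", "1"))
  expect_true(qp_is_zero(qp_sub(p, p)))
  expect_equal(as.character(qp_scale(q, "1/2")$coef), c("-1/2", "1/2"))
  # trailing zero coefficients are trimmed
  expect_equal(qp_degree(qp_sub(qpoly(c("0", "0", "3")),
                                qpoly(c("1", "0", "3")))), 0L)
})

test_that("evaluation and the Euler derivative", {
  p <- qpoly(c("1", "-3", "0", "2"))      # 1 - 3x + 2x^3
  expect_equal(as.character(qp_eval(p, "1/2")), "-1/4")
  expect_equal(qp_eval_num(p, c(0, 1, 2)), c(1, 0, 11))
  expect_equal(as.character(qp_that_deriv(p)$coef), c("0", "-3", "0", "6"))
})

test_that("root expansion and deflation round-trip", {
  r <- bigq(c("-1", "1/2", "5"))
  p <- qp_from_roots(r)
  expect_equal(qp_degree(p), 3L)
  for (i in seq_along(r)) expect_true(bq_is_zero(qp_eval(p, r[i])))
  d <- qp_deflate(p, r[1])
  expect_true(qp_equal(d, qp_from_roots(r[2:3])))
})

test_that("rational roots are found exactly", {
  roots <- function(p) sort(as.numeric(qp_rational_roots(p)))
  expect_equal(roots(qp_from_roots(bigq(c("-1", "-2", "-4")))), c(-4, -2, -1))
  expect_equal(roots(qp_from_roots(bigq(c("1/2", "5", "-3")))), c(-3, 0.5, 5))
  # multiple roots, zero roots, non-monic leading coefficient
  p <- qp_scale(qp_mul(qp_from_roots(bigq(c("2/3", "2/3", "0"))),
                       qpoly(c("1", "0", "1"))), "-6")
  expect_equal(as.character(qp_rational_roots(p)), c("0", "2/3"))
  # irrational roots are not reported
  expect_length(unclass(qp_rational_roots(qpoly(c("-2", "0", "1")))), 0L)
  # large-denominator root among irrational cofactors
  p <- qp_mul(qp_from_roots(bigq("-34171/31979")), qpoly(c("1", "1", "1")))
  expect_equal(as.character(qp_rational_roots(p)), "-34171/31979")
})

test_that("continued-fraction reconstruction", {
  expect_equal(rational_reconstruct(0.25), "1/4")
  expect_equal(rational_reconstruct(1 / 3), "1/3")
  expect_equal(rational_reconstruct(-34171 / 31979), "-34171/31979")
  expect_true(is.na(rational_reconstruct(pi, max_den = 10)))
})

test_that("rational functions in one indeterminate", {
  x <- qrf_var()
  f <- (x + as_qrf(1)) / (x - as_qrf(1))
  g <- f * (x - as_qrf(1)) - x           # == 1
  expect_true(qp_is_zero((g - as_qrf(1))$num))
  expect_equal(as.character(qrf_eval(f, "3")), "2")
  expect_error(qrf_eval(f, "1"), "pole")
  h <- (as_qrf(1) / x)^2
  expect_equal(as.character(qrf_eval(h, "1/5")), "25")
  expect_error(f / (x - x), "zero")
  expect_equal(as.character(qrf_eval(-f, "3")), "-2")
})
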