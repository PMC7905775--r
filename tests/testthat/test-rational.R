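test_that("construction and canonicalization", {
  expect_equal(as.character(bigq("2/4")), "1/2")
  expect_equal(as.character(bigq("-6/-4")), "3/2")
  expect_equal(as.character(bigq("4/-6")), "-2/3")
  expect_equal(as.character(bigq(7)), "7")
  expect_equal(as.character(bigq("0/5")), "0")
  expect_error(bigq(0.5), "1/2")
  expect_error(bigq(NaN))
  expect_error(bigq("1/0"))
})

test_that("exact arithmetic", {
  expect_true(bigq("1/3") + bigq("1/6") == bigq("1/2"))
  expect_true(bigq("1/3") - bigq("1/6") == bigq("1/6"))
  expect_true(bigq("2/3") * bigq("9/4") == bigq("3/2"))
  expect_true(bigq("2/3") / bigq("4/9") == bigq("3/2"))
  expect_true(-bigq("5/7") == bigq("-5/7"))
  # no precision loss at large magnitude
  big <- bigq(2)^200
  expect_equal(as.character(big - (big - bigq(1))), "1")
  expect_true(bigq("1/3") + bigq("2/3") == bigq(1))
  # vectorized with recycling against scalars
  v <- bigq(c("1/2", "1/3", "1/6"))
  expect_equal(as.character(sum(v)), "1")
  expect_equal(as.character(prod(v)), "1/36")
  expect_equal(as.character(v * bigq(6)), c("3", "2", "1"))
})

test_that("comparisons and signs", {
  expect_true(bigq("1/3") < bigq("1/2"))
  expect_true(bigq("-7/2") <= bigq("-7/2"))
  expect_true(bigq("10/5") == bigq(2))
  expect_true(bigq("1/3") != bigq("33333/100000"))
  expect_equal(bq_sign(bigq(c("-3/4", "0", "9"))), c(-1L, 0L, 1L))
  expect_equal(bq_is_zero(bigq(c("0", "1/9"))), c(TRUE, FALSE))
  expect_equal(as.character(abs(bigq(c("-3/4", "5")))), c("3/4", "5"))
})

test_that("powers", {
  expect_equal(as.character(bigq("2/3")^3), "8/27")
  expect_equal(as.character(bigq("2/3")^0), "1")
  expect_equal(as.character(bigq("2/3")^-2), "9/4")
  expect_error(bigq(2)^"a")
})

test_that("indexing, combination, conversion", {
  v <- bigq(c("1/2", "-3", "7/5"))
  expect_equal(as.character(v[2]), "-3")
  v[2] <- "4/9"
  expect_equal(as.character(v[2]), "4/9")
  expect_equal(as.character(c(v[1], bigq("1"))), c("1/2", "1"))
  expect_equal(as.character(rep(bigq("1/3"), 2)), c("1/3", "1/3"))
  expect_equal(as.numeric(bigq("1/2")), 0.5)
  expect_equal(as.numeric(bigq(c("1/4", "-8"))), c(0.25, -8))
})

test_that("exact square roots", {
  expect_equal(as.character(bq_sqrt(bigq("9/4"))), "3/2")
  expect_equal(as.character(bq_sqrt(bigq("0"))), "0")
  expect_true(is.na(unclass(bq_sqrt(bigq("2")))))
  expect_true(is.na(unclass(bq_sqrt(bigq("-9/4")))))
})
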