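test_that("system container validates its coefficients", {
  expect_error(lv_system(a0 = 1, a1 = c(1, 1), a2 = c(1, 1),
                         lambda = c(1, 1), b0 = c(1, 1), b1 = c(1, 1),
                         b2 = c(1, 1), mu = c(1, 1), gamma = c(1, 1)),
               "length 2")
  expect_error(lv_system(a0 = c(1, 1), a1 = c(1, 1), a2 = c(1, 1),
                         lambda = c(1, 1), b0 = c(1, 1), b1 = c(1, 1),
                         b2 = c(1, 1), mu = c(1, 1), gamma = c(0, 1)),
               "gamma")
  s <- fixture_coupled_lv()$system
  expect_true(system_equal(s, s))
  s2 <- s; s2$a1[1] <- s$a1[1] + bigq(1)
  expect_false(system_equal(s, s2))
})

test_that("A parameters and the p ratio table", {
  A <- solve_A(3, c("4/5", "2/5"))
  expect_equal(as.character(A$A2), c("-3/5", "-7/15"))
  expect_equal(as.character(A$p[[1]]), c("-5/4", "-5", "5/2"))
  expect_equal(as.character(A$p[[2]]), c("-5/2", "15", "15/8"))
  expect_error(solve_A(3, c("-1", "2/5")), "A2 = 0")
  # p denominator can vanish for unlucky A1
  expect_error(solve_A(2, c("0", "1")), "vanishing")
})

test_that("order-1 L pair satisfies its two defining equations identically", {
  p0 <- bigq("-5/4"); h0 <- bigq("7/3"); L3 <- bigq("2/9")
  L12 <- solve_LN_order1(p0, h0, L3)
  expect_true(bq_is_zero(bigq(1) + L12[1] + L12[2] + L3))
  expect_true(bq_is_zero(L12[1] + L12[2] * p0 + L3 * h0))
  expect_error(solve_LN_order1("1", "2", "3"), "singular")
})

test_that("unique L triple for n >= 2 matches the closed form", {
  L1 <- solve_LN_unique(3, "-5/4", "-5", "-34171/31979", "-170881/31979")
  expect_equal(as.character(L1), c("-9929/4410", "-8", "31979/4410"))
  L2 <- solve_LN_unique(3, "-5/2", "15", "-10021/7619", "139919/7619")
  expect_equal(as.character(L2), c("-12029/4410", "-2", "7619/4410"))
  # the triple satisfies the k = 0 and k = 1 balancing equations
  p <- bigq(c("-5/4", "-5")); h <- bigq(c("-34171/31979", "-170881/31979"))
  for (k in 0:1) {
    expect_true(bq_is_zero(bigq(k) + L1[1] + L1[2] * p[k + 1] +
                             L1[3] * h[k + 1]))
  }
  expect_error(solve_LN_unique(3, "1", "1", "2", "2"), "degenerate")
})

test_that("h from the balancing equation", {
  L <- c("-226/63", "136/315", "7/45")
  expect_equal(as.character(h_from_L(0, L, "-5/2")), "30")
  expect_equal(as.character(h_from_L(1, L, "15")), "-25")
  expect_equal(as.character(h_from_L(2, L, "15/8")), "5")
  expect_error(h_from_L(0, c("1", "1", "0"), "1"), "L3")
})

test_that("K pair satisfies its two defining equations identically", {
  K <- solve_K(3, "-625/617", "30", "10489/81")
  expect_equal(as.character(K), c("-130187/729", "-153745/729"))
  K2 <- solve_K(3, "30", "-625/617", "-153/617")
  expect_equal(as.character(K2), c("27/617", "-185/617"))
  h0l <- bigq(30); h0r <- bigq("-625/617"); K3 <- bigq("-153/617")
  expect_true(bq_is_zero(bigq(1) + K2[1] + K2[2] + bigq(3) * K3))
  expect_true(bq_is_zero(h0r + K2[1] * h0l + K2[2]))
  expect_error(solve_K(3, "1", "2", "3"), "singular")
})

test_that("zeroed denominator index bookkeeping", {
  expect_equal(required_zero_aes(3), 0L)
  expect_equal(required_zero_aes(6), 3L)
  expect_error(check_zero_aes(3, 2L), "exactly 0")
  expect_error(check_zero_aes(5, 2L), "exactly 2")
  expect_error(check_zero_aes(5, c(1L, 2L)), "indices 0 or 1")
  expect_error(check_zero_aes(5, c(2L, 5L)), "2..n-1")
  expect_equal(check_zero_aes(5, c(2L, 3L), exact = TRUE), c(2L, 3L))
  # relaxed mode allows fewer but never more
  expect_equal(check_zero_aes(5, 2L, exact = FALSE), 2L)
  expect_error(check_zero_aes(4, c(2L, 3L), exact = FALSE), "at most 1")
})

test_that("auxiliary container enforces structural invariants", {
  one <- c("1", "1")
  expect_error(lv_aux(2, A1 = one, L1 = one, L2 = one, L3 = one,
                      N1 = c("2", "2"), N2 = one, N3 = one,
                      K1 = one, K2 = one, K3 = one),
               "coincide")
  expect_error(lv_aux(2, A1 = one, L1 = one, L2 = one, L3 = one,
                      N1 = one, N2 = one, N3 = one,
                      K1 = one, K2 = one, K3 = c("0", "1")),
               "K3")
  expect_error(lv_aux(2, A1 = c("-1", "0"), L1 = one, L2 = one, L3 = one,
                      N1 = one, N2 = one, N3 = one,
                      K1 = one, K2 = one, K3 = one),
               "A1 = -1")
})

test_that("constraint residuals verify and discriminate", {
  fx <- fixture_coupled_lv()
  h <- list(bigq(c("-625/617", "-2965/617", "1580/617")),
            bigq(c("30", "-25", "5")))
  rep <- constraint_residuals(3, c("4/5", "2/5"), fx$aux$K3, h)
  expect_true(rep$pass)
  expect_named(rep$residuals,
               c("balance_l1_k2", "balance_l2_k2",
                 "coupling_l1_k1", "coupling_l1_k2",
                 "coupling_l2_k1", "coupling_l2_k2"))
  hbad <- h; hbad[[1]][3] <- hbad[[1]][3] + bigq("1/7")
  repb <- constraint_residuals(3, c("4/5", "2/5"), fx$aux$K3, hbad)
  expect_false(repb$pass)
})

test_that("condition-system solver reproduces the reference branch", {
  br <- solve_free_constraints(3, list(A11 = "4/5", A12 = "2/5",
                                       h12 = "-25", h22 = "5"))
  expect_length(br, 1L)
  b <- br[[1]]
  expect_equal(as.character(b$h[[1]]),
               c("-625/617", "-2965/617", "1580/617"))
  expect_equal(as.character(b$h[[2]]), c("30", "-25", "5"))
  expect_equal(as.character(b$K3), c("10489/81", "-153/617"))
  expect_true(b$report$pass)
})

test_that("condition-system solver handles the other schemas and errors", {
  # n = 1: free choices echoed as the single branch
  br1 <- solve_free_constraints(1, list(A11 = "1/2", A12 = "1/3",
                                        h01 = "2", h02 = "3",
                                        K31 = "5", K32 = "7"))
  expect_length(br1, 1L)
  expect_equal(as.character(br1[[1]]$K3), c("5", "7"))
  # n = 2: K3 determined by the coupling equations, then verified
  br2 <- solve_free_constraints(2, list(A11 = "1/2", A12 = "1/3",
                                        h01 = "2", h02 = "3",
                                        h11 = "4", h12 = "5"))
  if (length(br2) > 0L) expect_true(br2[[1]]$report$pass)
  expect_error(solve_free_constraints(3, list(A11 = "4/5")), "missing fixed")
  expect_error(solve_free_constraints(5, list(), zero_aes = c(1L, 2L)),
               "indices 0 or 1")
})

test_that("assembled system matches the bundled coupled instance exactly", {
  fx <- fixture_coupled_lv()
  s <- fx$system
  expect_equal(as.character(s$a0), c("5/3", "30/7"))
  expect_equal(as.character(s$a1), c("-16/9", "-172/63"))
  expect_equal(as.character(s$a2), c("-68/5", "68/315"))
  expect_equal(as.character(s$lambda), c("617/135", "7/180"))
  expect_equal(as.character(s$b0), c("153745/31467", "-740/153"))
  expect_equal(as.character(s$b1), c("-656207/377604", "6317/3213"))
  expect_equal(as.character(s$b2), c("617/135", "7/180"))
  expect_equal(as.character(s$mu), c("-68/5", "68/315"))
  expect_equal(as.character(s$gamma), c("-243/41956", "2468/459"))
})

test_that("every model coefficient is linear in the rate", {
  fx <- fixture_coupled_lv()
  sig <- c(1, 3, 2, 4)
  s1 <- assemble_system(fx$aux, sig, 1)
  s2 <- assemble_system(fx$aux, sig, 2)
  for (nm in names(s1)) expect_true(all(s2[[nm]] == bigq(2) * s1[[nm]]))
  expect_error(assemble_system(fx$aux, sig, 0), "eta")
  expect_error(assemble_system(fx$aux, c(0, 3, 2, 4), 1), "nonzero")
})

test_that("the flipped linear-term variant differs from the rederived one", {
  fx <- fixture_coupled_lv()
  sf <- assemble_system(fx$aux, c(1, 3, 2, 4), 1, b1_formula = "flipped_L1")
  expect_equal(as.character(sf$b1), c("564443/125868", "29369/3213"))
  # only b1 differs between the two variants
  sr <- fx$system
  for (nm in setdiff(names(sr), "b1")) {
    expect_true(all(sf[[nm]] == sr[[nm]]))
  }
})

test_that("full assembly ties ratios, solution, and system together", {
  fx <- fixture_coupled_lv()
  sol <- fx$solution
  expect_equal(as.character(sol$components$y2$num$coef),
               c("30", "-125", "75", "1"))
  expect_equal(as.character(sol$components$x1$den$coef),
               c("1", "5", "15", "1"))
  expect_error(assemble_full(3, list(A11 = "4/5", A12 = "2/5",
                                     h12 = "-25", h22 = "5"),
                             aes = c(1, 5), sigmas = c(1, 3, 2, 4),
                             eta = 1, t0 = 0),
               "length n")
  expect_error(assemble_full(4, list(A11 = "4/5", A12 = "2/5",
                                     h12 = "-25", h32 = "5"),
                             aes = c(1, 5, 1, 15), sigmas = c(1, 3, 2, 4),
                             eta = 1, t0 = 0, zero_aes = 2L),
               "must be zero")
})
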