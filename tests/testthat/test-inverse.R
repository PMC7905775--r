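test_that("structural coefficient constraints", {
  fx <- fixture_coupled_lv()
  rep <- check_coeff_constraints(fx$system)
  expect_true(rep$pass)
  bad <- fx$system
  bad$mu[1] <- bad$mu[1] + bigq(1)
  repb <- check_coeff_constraints(bad)
  expect_false(repb$pass)
  expect_false(bq_is_zero(repb$residuals$a2_minus_mu_l1))
  # zero coupling flagged via the guard (plain list sidesteps the
  # constructor's own gamma check)
  dec <- unclass(fx$system)
  dec$gamma <- bigq(c(0, 1))
  expect_false(check_coeff_constraints(dec)$pass)
  expect_true("decoupled" %in% check_coeff_constraints(dec)$guards_violated)
})

test_that("parameter recovery reproduces the generating branch", {
  fx <- fixture_coupled_lv()
  br <- recover_parameters(fx$system, 3, sigmas = c(1, 3, 2, 4))
  expect_length(br, 1L)
  b <- br[[1]]
  expect_equal(as.character(b$eta), "1")
  for (nm in c("A1", "L1", "L2", "L3", "N1", "N2", "N3", "K1", "K2", "K3")) {
    expect_true(all(b$aux[[nm]] == fx$aux[[nm]]))
  }
  expect_equal(as.character(b$h[[1]]),
               c("-625/617", "-2965/617", "1580/617"))
  expect_equal(as.character(b$h[[2]]), c("30", "-25", "5"))
})

test_that("amplitudes are constrained, not free gauge choices", {
  fx <- fixture_coupled_lv()
  # the eta-free balancing relation a1 + a0/sigma1 + mu sigma1 + b2 sigma2
  # must vanish per subsystem at any admissible amplitude choice
  s <- fx$system
  sig <- bigq(c(1, 3, 2, 4))
  for (l in 1:2) {
    s1 <- sig[c(1, 3)][l]; s2 <- sig[c(2, 4)][l]
    expect_true(bq_is_zero(s$a1[l] + s$a0[l] / s1 + s$mu[l] * s1 +
                             s$b2[l] * s2))
  }
  # the all-ones choice violates it, so recovery finds nothing there
  expect_length(recover_parameters(fx$system, 3), 0L)
})

test_that("recovery rejects perturbed systems and bad input", {
  fx <- fixture_coupled_lv()
  pert <- fx$system
  pert$b0[2] <- pert$b0[2] + bigq("1/1000")
  expect_length(recover_parameters(pert, 3, sigmas = c(1, 3, 2, 4)), 0L)
  # structural violation short-circuits for n >= 2
  pert2 <- fx$system
  pert2$mu[1] <- pert2$mu[1] + bigq(1)
  expect_length(recover_parameters(pert2, 3, sigmas = c(1, 3, 2, 4)), 0L)
  expect_error(recover_parameters(fx$system, 3, sigmas = c(1, 0, 2, 4)),
               "nonzero")
  expect_error(recover_parameters(fx$system, 3, sigmas = c(1, 2)),
               "four")
})

test_that("solution recovery completes a branch to a verified solution", {
  fx <- fixture_coupled_lv()
  br <- recover_parameters(fx$system, 3, sigmas = c(1, 3, 2, 4))[[1]]
  # with the generating free parameters the original solution returns
  sol <- recover_solution(fx$system, 3, br, aes = c(1, 5, 15), t0 = -5)
  for (nm in names(sol$components)) {
    expect_true(qp_equal(sol$components[[nm]]$num,
                         fx$solution$components[[nm]]$num))
  }
  expect_true(all(sol$aes == fx$solution$aes))
  # any other valid denominator/shift choice also verifies exactly
  sol2 <- recover_solution(fx$system, 3, br, aes = c(2, 1, 1), t0 = 7)
  expect_true(ode_residual(fx$system, sol2)$pass)
  expect_warning(recover_solution(fx$system, 3, br, aes = c(0, 5, 15)),
                 "reduces the effective order")
  expect_error(recover_solution(fx$system, 3, br, aes = c(1, 5)),
               "length n")
})

test_that("small forward/inverse round-trips across orders", {
  for (n in 1:2) {
    fix <- generate_fixture(n, seed = 40 + n, ranges = list(max_abs = 6))
    br <- recover_parameters(fix$system, n, sigmas = fix$sigmas,
                             zero_aes = fix$zero_aes)
    found <- any(vapply(br, function(b) {
      b$eta == fix$eta &&
        all(vapply(names(b$aux), function(nm) {
          all(b$aux[[nm]] == fix$aux[[nm]])
        }, logical(1)))
    }, logical(1)))
    expect_true(found)
  }
})
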