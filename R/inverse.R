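#' Structural coefficient constraints for higher-order solutions
#'
#' A system can only admit solitary solutions of order \eqn{n \ge 2} if its
#' quadratic and cross terms pair up exactly: \eqn{a_{2l} = \mu_l} and
#' \eqn{b_{2l} = \lambda_l} for both subsystems (a consequence of the L and
#' N triples coinciding). A zero diffusive coupling is flagged as
#' `decoupled`: such a model splits into two independent pair systems and
#' belongs with the pair-system tools instead.
#'
#' @param sys an [lv_system] (or any list carrying the same fields).
#' @return a [condition_report] with residuals `a2_minus_mu_l1`,
#'   `a2_minus_mu_l2`, `b2_minus_lambda_l1`, `b2_minus_lambda_l2`.
#' @export
check_coeff_constraints <- function(sys) {
  a2 <- bigq(sys$a2); mu <- bigq(sys$mu)
  b2 <- bigq(sys$b2); lambda <- bigq(sys$lambda)
  gamma <- bigq(sys$gamma)
  guards <- if (any(bq_is_zero(gamma))) "decoupled" else character(0)
  condition_report(
    list(a2_minus_mu_l1 = a2[1] - mu[1],
         a2_minus_mu_l2 = a2[2] - mu[2],
         b2_minus_lambda_l1 = b2[1] - lambda[1],
         b2_minus_lambda_l2 = b2[2] - lambda[2]),
    guards_violated = guards
  )
}

#' Recover auxiliary parameters and the rate from a model system
#'
#' The inverse direction: given the 18 model coefficients, a target order,
#' and a candidate amplitude set, finds every exact parameter branch
#' \eqn{(A, L, N, K, \eta)} that reproduces the system through the forward
#' coefficient map.
#'
#' The caller fixes the four amplitudes (default all 1). With them fixed,
#' every auxiliary quantity is a rational function of the single remaining
#' unknown \eqn{\eta}; the defining relations are inverted symbolically
#' (exact rational-function arithmetic in \eqn{\eta}) and the surviving
#' consistency conditions become univariate polynomial constraints whose
#' common rational roots are extracted and verified by exact reassembly.
#'
#' The amplitudes are *not* arbitrary: they enter the consistency
#' conditions (already the balancing sum forces
#' \eqn{a_{1l} + a_{0l}/\sigma_{1l} + \mu_l \sigma_{1l}
#' + b_{2l} \sigma_{2l} = 0}, independently of \eqn{\eta}), so a system
#' admits branches only at compatible amplitude choices. An empty result
#' for one choice therefore does not rule out branches at another; solving
#' for the amplitudes jointly is outside this function's univariate
#' elimination and the caller is expected to supply candidates (for
#' round-trip verification, the generating amplitudes).
#' For \eqn{n \ge 2} the structural constraints of
#' [check_coeff_constraints()] must hold first; violation yields an empty
#' branch list.
#'
#' The time shift and the denominator coefficients never enter the model
#' coefficients, so the recovered branches are independent of them by
#' construction.
#'
#' @param sys an [lv_system].
#' @param n target order.
#' @param sigmas the amplitude choice: length-4 exact vector
#'   \eqn{(\sigma_{11}, \sigma_{21}, \sigma_{12}, \sigma_{22})}, all
#'   nonzero; defaults to all 1.
#' @param zero_aes zeroed denominator indices assumed for the solution
#'   family (default \eqn{2, \dots, n-2} for \eqn{n > 3}); coupling
#'   constraints at these indices are vacuous and skipped.
#' @return a list of branches (possibly empty; nonexistence is a result,
#'   not an error), each with `aux` ([lv_aux]), `sigmas`, `eta`, and `h`
#'   (the recovered ratio table: a list of two length-`n` [bigq] vectors,
#'   zero at the zeroed indices).
#' @export
recover_parameters <- function(sys, n, sigmas = c(1, 1, 1, 1),
                               zero_aes = NULL) {
  n <- as.integer(n)
  if (is.null(zero_aes)) zero_aes <- default_zero_aes(n)
  zero_aes <- check_zero_aes(n, zero_aes)
  sigmas <- bigq(sigmas)
  if (length(sigmas) != 4L || any(bq_is_zero(sigmas))) {
    stop("sigmas must supply four nonzero amplitudes", call. = FALSE)
  }
  if (n >= 2L && !check_coeff_constraints(sys)$pass) return(list())
  if (any(bq_is_zero(sys$a0))) return(list())  # A2 = -eta*sigma1/a0 needs a0 != 0
  if (any(bq_is_zero(sys$b2))) return(list())  # L3 = b2*sigma2/eta must be nonzero

  s1 <- sigmas[c(1L, 3L)]
  s2 <- sigmas[c(2L, 4L)]
  eta <- qrf_var()
  cq <- function(v) as_qrf(bigq(v))
  nn <- bigq(n)

  constraints <- list()
  per_l <- list()
  for (l in 1:2) {
    r <- 3L - l
    A2 <- -eta * cq(s1[l] / sys$a0[l])
    A1 <- cq(-1) - cq(nn) * A2
    N1 <- cq(sys$a1[l]) / eta + A1 / A2
    N2 <- cq(sys$a2[l] * s1[l]) / eta
    N3 <- cq(sys$lambda[l] * s2[l]) / eta
    L2 <- cq(sys$mu[l] * s1[l]) / eta
    L3 <- cq(sys$b2[l] * s2[l]) / eta
    L1 <- if (n >= 2L) N1 else cq(-1) - L2 - L3
    K3 <- -eta * cq(s2[l] / (sys$gamma[l] * s2[r]))
    K2 <- cq(-sys$b0[l]) * K3 / (eta * cq(s2[l]))
    K1 <- K3 * (L1 - cq(sys$b1[l]) / eta) - cq(s2[l] / s2[r])
    p <- lapply(0:(n - 1L), function(k) {
      cq(1) / (cq(1) + cq(nn - bigq(k)) * A2)
    })
    h <- lapply(0:(n - 1L), function(k) {
      if (k %in% zero_aes) as_qrf(0)
      else -(cq(bigq(k)) + L1 + L2 * p[[k + 1L]]) / L3
    })
    if (n >= 2L) {
      constraints[[length(constraints) + 1L]] <- (cq(nn) + L1 + L2 + L3)$num
    } else {
      # order 1: L and N are independent triples sharing p0 and h0; the
      # L-sum holds by construction of L1, while the N side contributes
      # its sum and its constant-term equation as genuine conditions
      constraints[[length(constraints) + 1L]] <- (cq(1) + N1 + N2 + N3)$num
      constraints[[length(constraints) + 1L]] <-
        (N1 + N2 * p[[1L]] + N3 * h[[1L]])$num
    }
    constraints[[length(constraints) + 1L]] <-
      (cq(1) + K1 + K2 + cq(nn) * K3)$num
    per_l[[l]] <- list(A1 = A1, N1 = N1, N2 = N2, N3 = N3,
                       L1 = L1, L2 = L2, L3 = L3,
                       K1 = K1, K2 = K2, K3 = K3, h = h)
  }
  for (l in 1:2) {
    r <- 3L - l
    for (k in c(0L, active_indices(n, zero_aes, 1L))) {
      e <- per_l[[r]]$h[[k + 1L]] + per_l[[l]]$K1 * per_l[[l]]$h[[k + 1L]] +
        per_l[[l]]$K2 + per_l[[l]]$K3 * cq(bigq(k)) * per_l[[l]]$h[[k + 1L]]
      constraints[[length(constraints) + 1L]] <- e$num
    }
  }

  constraints <- Filter(function(p) !qp_is_zero(p), constraints)
  if (length(constraints) == 0L) {
    stop("no nontrivial constraint on the rate: the inverse problem is ",
         "underdetermined for this system", call. = FALSE)
  }
  cands <- qp_rational_roots(constraints[[1L]])
  for (p in constraints[-1L]) {
    if (length(cands) == 0L) break
    keep <- vapply(seq_along(cands), function(i) {
      bq_is_zero(qp_eval(p, cands[i]))
    }, logical(1))
    cands <- cands[keep]
  }
  if (length(cands) > 0L) cands <- cands[!bq_is_zero(cands)]

  branches <- list()
  for (i in seq_along(cands)) {
    et <- cands[i]
    br <- tryCatch({
      ev <- function(v) qrf_eval(v, et)
      g2 <- function(nm) c(ev(per_l[[1L]][[nm]]), ev(per_l[[2L]][[nm]]))
      aux <- lv_aux(n, A1 = g2("A1"),
                    L1 = g2("L1"), L2 = g2("L2"), L3 = g2("L3"),
                    N1 = g2("N1"), N2 = g2("N2"), N3 = g2("N3"),
                    K1 = g2("K1"), K2 = g2("K2"), K3 = g2("K3"))
      if (!system_equal(assemble_system(aux, sigmas, et), sys)) {
        stop("branch fails exact reassembly")
      }
      h <- lapply(per_l, function(pl) do.call(c, lapply(pl$h, ev)))
      list(aux = aux, sigmas = sigmas, eta = et, h = h)
    }, error = function(e) NULL)
    if (!is.null(br)) branches[[length(branches) + 1L]] <- br
  }
  branches
}

#' Recover a full solitary solution from an inverse branch
#'
#' Completes a branch returned by [recover_parameters()] to a concrete
#' closed-form solution by choosing the remaining free parameters: the
#' shared denominator coefficients and the time shift (the amplitudes are
#' already fixed by the branch's amplitudes). The result is verified exactly
#' against the system before being returned.
#'
#' @param sys the [lv_system] the branch was recovered from.
#' @param n order.
#' @param branch one element of the list returned by
#'   [recover_parameters()].
#' @param aes length-`n` exact vector of denominator coefficients; entries
#'   at the zeroed indices must be zero. A zero leading entry (`aes[1]`)
#'   is accepted with a warning: it makes the transformed variable a
#'   common factor of all numerators and the denominator, silently
#'   reducing the effective order.
#' @param t0 exact time shift (free; default 0).
#' @param zero_aes zeroed indices, matching the branch (default
#'   \eqn{2, \dots, n-2} for \eqn{n > 3}).
#' @return an [lv_solution] satisfying `sys` identically.
#' @export
recover_solution <- function(sys, n, branch, aes, t0 = 0, zero_aes = NULL) {
  n <- as.integer(n)
  if (is.null(zero_aes)) zero_aes <- default_zero_aes(n)
  zero_aes <- check_zero_aes(n, zero_aes)
  aes <- bigq(aes)
  if (length(aes) != n) stop("aes must have length n", call. = FALSE)
  if (length(zero_aes) > 0L && !all(bq_is_zero(aes[zero_aes + 1L]))) {
    stop("aes entries at the zeroed indices (", paste(zero_aes, collapse = ", "),
         ") must be zero", call. = FALSE)
  }
  if (bq_is_zero(aes[1L])) {
    warning("aes[1] = 0 reduces the effective order: the transformed ",
            "variable divides all numerators and the denominator")
  }
  A <- solve_A(n, branch$aux$A1)
  sol <- lv_solution(n, branch$eta, t0, branch$sigmas, aes,
                     list(x1 = A$p[[1L]], y1 = branch$h[[1L]],
                          x2 = A$p[[2L]], y2 = branch$h[[2L]]))
  rep <- ode_residual(sys, sol)
  if (!rep$pass) {
    bad <- names(rep$residuals)[!vapply(rep$residuals, function(r) {
      all(bq_is_zero(r))
    }, logical(1))]
    stop("recovered solution fails the exact residual check: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sol
}
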