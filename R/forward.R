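#' Coupled four-equation model system
#'
#' The 18 exact coefficients of the model
#' \deqn{x_l' = a_{0l} + a_{1l} x_l + a_{2l} x_l^2 + \lambda_l x_l y_l,}
#' \deqn{y_l' = b_{0l} + b_{1l} y_l + b_{2l} y_l^2 + \mu_l x_l y_l
#'       + \gamma_l (y_r - y_l), \qquad l = 1, 2,\; r \neq l,}
#' two Riccati pairs coupled multiplicatively within a pair
#' (\eqn{\lambda, \mu}) and diffusively between pairs (\eqn{\gamma}).
#'
#' @param a0,a1,a2,lambda,b0,b1,b2,mu,gamma length-2 exact vectors, indexed
#'   by the subsystem \eqn{l \in \{1, 2\}}; `gamma` must be nonzero in both
#'   entries (a zero would decouple the model into two independent pairs).
#' @return an object of class `lv_system`.
#' @export
lv_system <- function(a0, a1, a2, lambda, b0, b1, b2, mu, gamma) {
  out <- list(a0 = bigq(a0), a1 = bigq(a1), a2 = bigq(a2),
              lambda = bigq(lambda), b0 = bigq(b0), b1 = bigq(b1),
              b2 = bigq(b2), mu = bigq(mu), gamma = bigq(gamma))
  for (nm in names(out)) {
    if (length(out[[nm]]) != 2L) {
      stop("coefficient ", nm, " must have length 2 (one value per subsystem)",
           call. = FALSE)
    }
  }
  if (any(bq_is_zero(out$gamma))) {
    stop("gamma must be nonzero: a zero diffusive coupling decouples the ",
         "model into two independent pair systems", call. = FALSE)
  }
  structure(out, class = "lv_system")
}

#' @export
print.lv_system <- function(x, ...) {
  for (l in 1:2) {
    cat("x", l, "' = ", unclass(x$a0[l]), " + ", unclass(x$a1[l]), " x + ",
        unclass(x$a2[l]), " x^2 + ", unclass(x$lambda[l]), " x y\n",
        sep = "")
    cat("y", l, "' = ", unclass(x$b0[l]), " + ", unclass(x$b1[l]), " y + ",
        unclass(x$b2[l]), " y^2 + ", unclass(x$mu[l]), " x y + ",
        unclass(x$gamma[l]), " (y_other - y)\n", sep = "")
  }
  invisible(x)
}

#' Exact equality of two model systems
#'
#' @param s1,s2 [lv_system] objects.
#' @return `TRUE` iff all 18 coefficients match exactly.
#' @export
system_equal <- function(s1, s2) {
  all(vapply(names(s1), function(nm) all(s1[[nm]] == s2[[nm]]), logical(1)))
}

#' Auxiliary parameter set
#'
#' The auxiliary quantities linking model coefficients to solitary-solution
#' coefficients: the A pair, the L/N/K triples (per subsystem \eqn{l}), and
#' the order \eqn{n}. `A2` is always the derived value \eqn{-(1 + A_1)/n}.
#' For \eqn{n \ge 2} the L and N triples necessarily coincide.
#'
#' @param n order.
#' @param A1 length-2 exact vector \eqn{(A_{11}, A_{12})}.
#' @param L1,L2,L3,N1,N2,N3,K1,K2,K3 length-2 exact vectors.
#' @return an object of class `lv_aux`.
#' @export
lv_aux <- function(n, A1, L1, L2, L3, N1, N2, N3, K1, K2, K3) {
  A1 <- bigq(A1)
  A2 <- -(bigq(1) + A1) / bigq(n)
  if (any(bq_is_zero(A2))) {
    stop("A1 = -1 forces A2 = 0, contradicting A2 = -eta*sigma/a0 with ",
         "nonzero eta and sigma", call. = FALSE)
  }
  out <- list(n = as.integer(n), A1 = A1, A2 = A2,
              L1 = bigq(L1), L2 = bigq(L2), L3 = bigq(L3),
              N1 = bigq(N1), N2 = bigq(N2), N3 = bigq(N3),
              K1 = bigq(K1), K2 = bigq(K2), K3 = bigq(K3))
  for (nm in setdiff(names(out), "n")) {
    if (length(out[[nm]]) != 2L) stop(nm, " must have length 2", call. = FALSE)
  }
  if (n >= 2L &&
      !(all(out$L1 == out$N1) && all(out$L2 == out$N2) &&
        all(out$L3 == out$N3))) {
    stop("for n >= 2 the L and N triples must coincide", call. = FALSE)
  }
  if (any(bq_is_zero(out$K3))) {
    stop("K3 must be nonzero (K3 = -eta*sigma2l/(gamma*sigma2r))",
         call. = FALSE)
  }
  structure(out, class = "lv_aux")
}

#' @export
print.lv_aux <- function(x, ...) {
  cat("<lv_aux> order ", x$n, "\n", sep = "")
  for (nm in c("A1", "A2", "L1", "L2", "L3", "N1", "N2", "N3",
               "K1", "K2", "K3")) {
    cat("  ", nm, ": ", paste(unclass(x[[nm]]), collapse = "  "), "\n",
        sep = "")
  }
  invisible(x)
}

#' A parameters and the p ratio table
#'
#' From the free choices \eqn{A_{1l}} derives \eqn{A_{2l} = -(1 + A_{1l})/n}
#' and the numerator-to-denominator coefficient ratios of the x components,
#' \deqn{p_{kl} = \frac{1}{1 + (n - k) A_{2l}}, \qquad k = 0, \dots, n - 1.}
#'
#' @param n order.
#' @param A1 length-2 exact vector; entries must differ from \eqn{-1}.
#' @return a list with `A1`, `A2` (length-2 [bigq]) and `p` (list of two
#'   length-`n` [bigq] vectors, element `k + 1` holding \eqn{p_{kl}}).
#' @examples
#' solve_A(3, c("4/5", "2/5"))$p[[1]]  # -5/4, -5, 5/2
#' @export
solve_A <- function(n, A1) {
  A1 <- bigq(A1)
  if (length(A1) != 2L) stop("A1 must have length 2", call. = FALSE)
  A2 <- -(bigq(1) + A1) / bigq(n)
  if (any(bq_is_zero(A2))) {
    stop("A1 = -1 gives A2 = 0, which contradicts A2 = -eta*sigma/a0",
         call. = FALSE)
  }
  p <- lapply(1:2, function(l) {
    den <- bigq(1) + bigq(n - (0:(n - 1))) * A2[l]
    if (any(bq_is_zero(den))) {
      k <- (0:(n - 1))[bq_is_zero(den)][1L]
      stop("vanishing p denominator 1 + (n-k)A2 at k = ", k, ", l = ", l,
           call. = FALSE)
    }
    bigq(1) / den
  })
  list(A1 = A1, A2 = A2, p = p)
}

#' L (or N) pair for order 1 given the free third entry
#'
#' For \eqn{n = 1} the two balancing equations leave one degree of freedom;
#' given \eqn{L_3} the remaining pair is
#' \deqn{L_1 = \frac{(1 + L_3) p_0 - L_3 h_0}{1 - p_0}, \qquad
#'       L_2 = \frac{L_3 (h_0 - 1) - 1}{1 - p_0},}
#' which satisfies \eqn{1 + L_1 + L_2 + L_3 = 0} and
#' \eqn{L_1 + L_2 p_0 + L_3 h_0 = 0} identically.
#'
#' @param p0,h0 constant-term ratios of the x and y components.
#' @param L3 free exact value.
#' @return a length-2 [bigq] vector \eqn{(L_1, L_2)}.
#' @export
solve_LN_order1 <- function(p0, h0, L3) {
  p0 <- bigq(p0); h0 <- bigq(h0); L3 <- bigq(L3)
  if (p0 == bigq(1)) stop("p0 = 1 makes the order-1 L system singular",
                          call. = FALSE)
  d <- bigq(1) - p0
  c(((bigq(1) + L3) * p0 - L3 * h0) / d,
    (L3 * (h0 - bigq(1)) - bigq(1)) / d)
}

#' The unique L = N triple for orders two and above
#'
#' For \eqn{n \ge 2} the balancing systems for L and N share the unique
#' solution
#' \deqn{L_1 = \frac{(p_1 n - 1) h_0 - p_0 (n h_1 - 1)}{D}, \quad
#'       L_2 = \frac{(1 - n) h_0 - 1 + n h_1}{D}, \quad
#'       L_3 = \frac{(n - 1) p_0 + 1 - n p_1}{D},}
#' with \eqn{D = (1 - p_1) h_0 + (h_1 - 1) p_0 + (p_1 - h_1)}; the
#' configuration is degenerate (no unique triple) when \eqn{D = 0}.
#'
#' @param n order, at least 2.
#' @param p0,p1,h0,h1 exact ratio values for one subsystem.
#' @return a length-3 [bigq] vector \eqn{(L_1, L_2, L_3)}.
#' @export
solve_LN_unique <- function(n, p0, p1, h0, h1) {
  stopifnot(n >= 2L)
  p0 <- bigq(p0); p1 <- bigq(p1); h0 <- bigq(h0); h1 <- bigq(h1)
  nn <- bigq(n)
  D <- (bigq(1) - p1) * h0 + (h1 - bigq(1)) * p0 + (p1 - h1)
  if (bq_is_zero(D)) {
    stop("degenerate ratio configuration: the L/N system denominator ",
         "(1-p1)h0 + (h1-1)p0 + (p1-h1) vanishes", call. = FALSE)
  }
  c(((p1 * nn - bigq(1)) * h0 - p0 * (nn * h1 - bigq(1))) / D,
    ((bigq(1) - nn) * h0 - bigq(1) + nn * h1) / D,
    ((nn - bigq(1)) * p0 + bigq(1) - nn * p1) / D)
}

#' h ratio from an L triple
#'
#' Rearranges the balancing equation
#' \eqn{k + L_1 + L_2 p_k + L_3 h_k = 0} for the y-component ratio:
#' \eqn{h_k = -(k + L_1 + L_2 p_k)/L_3}.
#'
#' @param k coefficient index.
#' @param L length-3 exact vector \eqn{(L_1, L_2, L_3)}; \eqn{L_3 \neq 0}.
#' @param p_k the x-component ratio at the same index.
#' @return a length-one [bigq].
#' @export
h_from_L <- function(k, L, p_k) {
  L <- bigq(L)
  if (bq_is_zero(L[3])) stop("L3 = 0: h is not determined by this equation",
                             call. = FALSE)
  -(bigq(k) + L[1] + L[2] * bigq(p_k)) / L[3]
}

#' K pair from the leading and constant-term coupling equations
#'
#' \deqn{K_1 = \frac{h_{0r} - n K_3 - 1}{1 - h_{0l}}, \qquad
#'       K_2 = \frac{(n K_3 + 1) h_{0l} - h_{0r}}{1 - h_{0l}},}
#' which satisfy \eqn{1 + K_1 + K_2 + n K_3 = 0} and
#' \eqn{h_{0r} + K_1 h_{0l} + K_2 = 0} identically.
#'
#' @param n order.
#' @param h0_self \eqn{h_{0l}} of the subsystem owning the K triple; must
#'   differ from 1.
#' @param h0_other \eqn{h_{0r}} of the other subsystem.
#' @param K3 the free (or separately solved) third entry.
#' @return a length-2 [bigq] vector \eqn{(K_1, K_2)}.
#' @export
solve_K <- function(n, h0_self, h0_other, K3) {
  h0l <- bigq(h0_self); h0r <- bigq(h0_other); K3 <- bigq(K3)
  if (h0l == bigq(1)) stop("h0 = 1 makes the K system singular", call. = FALSE)
  nn <- bigq(n)
  d <- bigq(1) - h0l
  c((h0r - nn * K3 - bigq(1)) / d,
    ((nn * K3 + bigq(1)) * h0l - h0r) / d)
}

#' Number of denominator coefficients that must vanish
#'
#' Orders up to three need no additional constraints; above three, exactly
#' \eqn{n - 3} of the shared denominator coefficients \eqn{\ae_k} must be
#' zero for the condition system to be solvable.
#'
#' @param n order.
#' @return `max(0, n - 3)`.
#' @export
required_zero_aes <- function(n) {
  stopifnot(n >= 1L)
  max(0L, as.integer(n) - 3L)
}

default_zero_aes <- function(n) {
  if (n <= 3L) integer(0) else 2:(as.integer(n) - 2L)
}

active_indices <- function(n, zero_aes, from) {
  if (from > n - 1L) return(integer(0))
  ks <- seq.int(from, n - 1L)
  ks[!(ks %in% zero_aes)]
}

check_zero_aes <- function(n, zero_aes, exact = TRUE) {
  zero_aes <- as.integer(zero_aes)
  if (exact && length(zero_aes) != required_zero_aes(n)) {
    stop("order ", n, " requires exactly ", required_zero_aes(n),
         " zeroed denominator coefficients; got ", length(zero_aes),
         call. = FALSE)
  }
  if (!exact && length(zero_aes) > required_zero_aes(n)) {
    stop("order ", n, " admits at most ", required_zero_aes(n),
         " zeroed denominator coefficients", call. = FALSE)
  }
  if (any(zero_aes %in% c(0L, 1L))) {
    stop("zeroing indices 0 or 1 is not supported: index 0 silently reduces ",
         "the effective order and indices 0-1 feed the closed-form L/N ",
         "solution", call. = FALSE)
  }
  if (any(zero_aes >= n)) stop("zeroed indices must lie in 2..n-1",
                               call. = FALSE)
  zero_aes
}

#' Residuals of the remaining balancing and coupling constraints
#'
#' Given the free A choices, the K3 pair, and the complete h table, derives
#' p, the L = N triples, and the K pairs, then evaluates every remaining
#' constraint exactly: the balancing equations
#' \eqn{k + L_{1l} + L_{2l} p_{kl} + L_{3l} h_{kl} = 0} for
#' \eqn{k = 2, \dots, n-1} and the coupling equations
#' \eqn{h_{kr} + K_{1l} h_{kl} + K_{2l} + K_{3l} k h_{kl} = 0} for
#' \eqn{k = 1, \dots, n-1}. Equations at zeroed denominator indices hold
#' trivially and are skipped.
#'
#' @param n order, at least 2.
#' @param A1 length-2 exact vector.
#' @param K3 length-2 exact vector.
#' @param h list of two length-`n` exact vectors (`h[[l]][k + 1]` is
#'   \eqn{h_{kl}}).
#' @param zero_aes integer vector of zeroed denominator indices (in
#'   \eqn{\{2, \dots, n-1\}}).
#' @return a [condition_report] with one named residual per constraint.
#' @export
constraint_residuals <- function(n, A1, K3, h, zero_aes = integer(0)) {
  stopifnot(n >= 2L)
  zero_aes <- as.integer(zero_aes)
  K3 <- bigq(K3)
  h <- lapply(h, bigq)
  A <- solve_A(n, A1)
  L <- lapply(1:2, function(l) {
    solve_LN_unique(n, A$p[[l]][1], A$p[[l]][2], h[[l]][1], h[[l]][2])
  })
  K12 <- lapply(1:2, function(l) {
    r <- 3L - l
    solve_K(n, h[[l]][1], h[[r]][1], K3[l])
  })
  res <- list()
  for (l in 1:2) {
    for (k in active_indices(n, zero_aes, 2L)) {
      res[[paste0("balance_l", l, "_k", k)]] <-
        bigq(k) + L[[l]][1] + L[[l]][2] * A$p[[l]][k + 1L] +
        L[[l]][3] * h[[l]][k + 1L]
    }
  }
  for (l in 1:2) {
    r <- 3L - l
    for (k in active_indices(n, zero_aes, 1L)) {
      res[[paste0("coupling_l", l, "_k", k)]] <-
        h[[r]][k + 1L] + K12[[l]][1] * h[[l]][k + 1L] + K12[[l]][2] +
        K3[l] * bigq(k) * h[[l]][k + 1L]
    }
  }
  condition_report(res)
}

# Gaussian elimination over exact rational functions; A is a list of rows,
# each a list of qrf, b a list of qrf. Returns list of qrf solutions or
# NULL if a pivot cannot be found (structurally singular system).
solve_affine_system <- function(A, b) {
  m <- length(A)
  nvar <- length(A[[1L]])
  stopifnot(m == nvar, length(b) == m)
  for (col in seq_len(nvar)) {
    piv <- NULL
    for (row in col:m) {
      if (!qp_is_zero(A[[row]][[col]]$num)) { piv <- row; break }
    }
    if (is.null(piv)) return(NULL)
    if (piv != col) {
      tmp <- A[[col]]; A[[col]] <- A[[piv]]; A[[piv]] <- tmp
      tmp <- b[[col]]; b[[col]] <- b[[piv]]; b[[piv]] <- tmp
    }
    for (row in seq_len(m)) {
      if (row == col) next
      if (qp_is_zero(A[[row]][[col]]$num)) next
      f <- A[[row]][[col]] / A[[col]][[col]]
      for (j in col:nvar) A[[row]][[j]] <- A[[row]][[j]] - f * A[[col]][[j]]
      b[[row]] <- b[[row]] - f * b[[col]]
    }
  }
  lapply(seq_len(nvar), function(i) b[[i]] / A[[i]][[i]])
}

#' Solve the condition system for the dependent unknowns
#'
#' Completes a set of free choices to full solution branches of the
#' balancing/coupling condition system. The free-choice schema depends on
#' the order:
#' \itemize{
#'   \item `n = 1`: no constraints remain; `fixed` must carry `A11`, `A12`,
#'     `h01`, `h02`, `K31`, `K32` (all free) and is echoed as one branch.
#'   \item `n = 2`: `fixed` carries `A11`, `A12`, `h01`, `h02`, `h11`,
#'     `h12`; the two K3 values are each determined by one linear coupling
#'     equation.
#'   \item `n >= 3`: `fixed` carries `A11`, `A12` and the y2 ratios
#'     `h<k>2` for every active index \eqn{k \ge 1} (for `n = 3`: `h12`,
#'     `h22`). The solver eliminates exactly: `h02` from the l = 2
#'     balancing equation; the l = 1 ratios and `K32` from the equations
#'     linear in them (with `h01` symbolic); `K31` by elimination, leaving
#'     univariate polynomial constraints on `h01` whose rational roots are
#'     extracted and verified exactly.
#' }
#' Every returned branch is re-verified against [constraint_residuals()];
#' an infeasible system yields an empty list, not an error. Real
#' non-rational branch points are outside the exact scope and are dropped
#' (they cannot be represented in exact rational arithmetic).
#'
#' Supplying *fewer* than the required \eqn{n - 3} zeroed indices is
#' accepted here (only): the condition system is then overdetermined and
#' generically has no solution, which this function reports as an empty
#' branch list — the constructive face of the order dichotomy.
#' [assemble_full()] always demands exactly \eqn{n - 3}.
#'
#' @param n order.
#' @param fixed named list of exact free choices (see schema above).
#' @param zero_aes zeroed denominator indices; defaults to
#'   \eqn{2, \dots, n-2} when \eqn{n > 3}.
#' @return a list of branches, each a list with `A1`, `h` (list of two
#'   length-`n` [bigq] vectors), `K3`, and `report` (the verifying
#'   [condition_report]).
#' @examples
#' \donttest{
#' br <- solve_free_constraints(3, list(A11 = "4/5", A12 = "2/5",
#'                                      h12 = "139919/7619",
#'                                      h22 = "39493/15238"))
#' as.character(br[[1]]$h[[2]][1])  # h02 = "-10021/7619"
#' }
#' @export
solve_free_constraints <- function(n, fixed, zero_aes = NULL) {
  n <- as.integer(n)
  if (is.null(zero_aes)) zero_aes <- default_zero_aes(n)
  zero_aes <- check_zero_aes(n, zero_aes, exact = FALSE)
  need <- function(nms) {
    miss <- setdiff(nms, names(fixed))
    if (length(miss) > 0L) {
      stop("missing fixed choices: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    lapply(fixed[nms], bigq)
  }
  if (n == 1L) {
    f <- need(c("A11", "A12", "h01", "h02", "K31", "K32"))
    A1 <- c(f$A11, f$A12)
    solve_A(1L, A1)  # guard check only
    return(list(list(A1 = A1,
                     h = list(f$h01, f$h02),
                     K3 = c(f$K31, f$K32),
                     report = condition_report(list()))))
  }
  if (n == 2L) {
    f <- need(c("A11", "A12", "h01", "h02", "h11", "h12"))
    A1 <- c(f$A11, f$A12)
    h <- list(c(f$h01, f$h11), c(f$h02, f$h12))
    K3 <- bigq(c(0, 0))
    for (l in 1:2) {
      r <- 3L - l
      if (h[[l]][1] == bigq(1)) return(list())
      # coupling equation at k=1, h1r + K1l h1l + K2l + K3l h1l = 0,
      # multiplied by (1 - h0l):
      # h1r(1-h0l) + (h0r - nK3 - 1)h1l + (nK3+1)h0l - h0r + K3 h1l (1-h0l) = 0
      # grouped as P + K3l * Q = 0:
      P <- h[[r]][2] * (bigq(1) - h[[l]][1]) +
        (h[[r]][1] - bigq(1)) * h[[l]][2] + h[[l]][1] - h[[r]][1]
      Q <- -bigq(n) * h[[l]][2] + bigq(n) * h[[l]][1] +
        h[[l]][2] * (bigq(1) - h[[l]][1])
      if (bq_is_zero(Q)) return(list())
      K3[l] <- -P / Q
    }
    if (any(bq_is_zero(K3))) return(list())
    rep <- tryCatch(constraint_residuals(n, A1, K3, h, zero_aes),
                    error = function(e) NULL)
    if (is.null(rep) || !rep$pass) return(list())
    return(list(list(A1 = A1, h = h, K3 = K3, report = rep)))
  }
  # ---- n >= 3: sequential exact elimination ------------------------------
  k93 <- active_indices(n, zero_aes, 1L)   # coupling indices
  k88 <- active_indices(n, zero_aes, 2L)   # balancing indices
  f <- need(c("A11", "A12", paste0("h", k93, "2")))
  A1 <- c(f$A11, f$A12)
  A <- solve_A(n, A1)
  h2 <- rep(bigq("0"), n)                  # h_k2 table; h02 solved below
  for (k in k93) h2[k + 1L] <- f[[paste0("h", k, "2")]]
  nn <- bigq(n)

  # stage 1: h02 from the l=2 balancing equations (each linear in h02 after
  # clearing the L-triple denominator D2)
  p2 <- A$p[[2L]]
  bal2_poly <- function(k) {
    # (k + L12 + L22 p_k2 + L32 h_k2) * D2 as a polynomial in x = h02
    x <- qrf_var()
    D2 <- (as_qrf(bigq(1) - p2[2]) * x) + as_qrf((h2[2] - bigq(1)) * p2[1] +
                                                 (p2[2] - h2[2]))
    L12 <- (as_qrf(p2[2] * nn - bigq(1)) * x) -
      as_qrf(p2[1] * (nn * h2[2] - bigq(1)))
    L22 <- (as_qrf(bigq(1) - nn) * x) + as_qrf(nn * h2[2] - bigq(1))
    L32 <- as_qrf((nn - bigq(1)) * p2[1] + bigq(1) - nn * p2[2])
    e <- as_qrf(bigq(k)) * D2 + L12 + L22 * as_qrf(p2[k + 1L]) +
      L32 * as_qrf(h2[k + 1L])
    e$num
  }
  h02_cands <- qp_rational_roots(bal2_poly(k88[1L]))
  if (length(k88) > 1L) {
    for (k in k88[-1L]) {
      pk <- bal2_poly(k)
      keep <- vapply(seq_along(h02_cands), function(i) {
        bq_is_zero(qp_eval(pk, h02_cands[i]))
      }, logical(1))
      h02_cands <- h02_cands[keep]
    }
  }
  branches <- list()
  for (ih in seq_along(h02_cands)) {
    h02 <- h02_cands[ih]
    if (h02 == bigq(1)) next
    h2b <- h2; h2b[1L] <- h02
    br <- solve_branch_l1(n, A, h2b, k93, k88, zero_aes)
    branches <- c(branches, br)
  }
  branches
}

# Inner elimination for the l=1 unknowns given a solved h02 (stored in
# h2[1]). Unknowns linear in x = h01: u = (h_k1 for k in k93, K32); then
# K31 eliminated from the l=1 coupling equations, leaving univariate
# polynomial constraints on h01.
solve_branch_l1 <- function(n, A, h2, k93, k88, zero_aes) {
  nn <- bigq(n)
  x <- qrf_var()                 # symbol for h01
  p1 <- A$p[[1L]]
  nu <- length(k93) + 1L         # unknowns: h_k1 (k in k93), K32
  zero <- as_qrf(0)
  rows <- list(); rhs <- list()

  # l=1 balancing equations (linear in h01 and the h_k1 jointly): multiply
  # by D1 = (1-p11)h01 + (h11-1)p01 + (p11-h11); h11 is unknown u_1 when
  # 1 is active (it always is, since zeroing index 1 is rejected).
  i1 <- match(1L, k93)
  for (k in k88) {
    # expand (k*D1 + numL11 + numL21*p_k1 + numL31*h_k1) = 0 in unknowns
    # (x = h01, u_i1 = h11, u_k = h_k1)
    row <- rep(list(zero), nu); b <- as_qrf(0)
    kk <- bigq(k)
    # k*D1: k(1-p11)x + k p01 u_i1 - k p01 + k p11 - k u_i1
    b <- b - as_qrf(kk) * ((as_qrf(bigq(1) - p1[2]) * x) +
                           as_qrf(p1[2] - p1[1]))
    row[[i1]] <- row[[i1]] - as_qrf(kk * p1[1] - kk)
    # numL11 = (p11 n - 1)x - p01 n u_i1 + p01
    b <- b - ((as_qrf(p1[2] * nn - bigq(1)) * x) + as_qrf(p1[1]))
    row[[i1]] <- row[[i1]] + as_qrf(p1[1] * nn)
    # numL21 * p_k1 = ((1-n)x - 1 + n u_i1) p_k1
    b <- b - as_qrf(p1[k + 1L]) * ((as_qrf(bigq(1) - nn) * x) -
                                   as_qrf(bigq(1)))
    row[[i1]] <- row[[i1]] - as_qrf(nn * p1[k + 1L])
    # numL31 * h_k1 with numL31 = (n-1)p01 + 1 - n p11 (constant)
    ik <- match(k, k93)
    row[[ik]] <- row[[ik]] -
      as_qrf((nn - bigq(1)) * p1[1] + bigq(1) - nn * p1[2])
    # equation is  sum(row_i * u_i) = b  after moving knowns right; the
    # loop above accumulated -(lhs terms) on the matching side, so flip:
    rows[[length(rows) + 1L]] <- lapply(row, function(e) -e)
    rhs[[length(rhs) + 1L]] <- b
  }

  # l=2 coupling equations, multiplied by (1 - h02):
  # h_k1 (1-h02) + (x - n K32 - 1) h_k2 + (n K32 + 1) h02 - x
  #   + K32 k h_k2 (1-h02) = 0
  h02 <- h2[1L]
  for (k in k93) {
    row <- rep(list(zero), nu); b <- as_qrf(0)
    ik <- match(k, k93)
    row[[ik]] <- row[[ik]] + as_qrf(bigq(1) - h02)
    b <- b - (x * as_qrf(h2[k + 1L]))                 # + x h_k2 -> move right
    b <- b + as_qrf(h2[k + 1L])                        # - h_k2
    row[[nu]] <- row[[nu]] - as_qrf(nn * h2[k + 1L])   # - n K32 h_k2
    row[[nu]] <- row[[nu]] + as_qrf(nn * h02)          # + n K32 h02
    b <- b - as_qrf(h02)                               # + h02 -> move right
    b <- b + x                                         # - x -> move right
    row[[nu]] <- row[[nu]] +
      as_qrf(bigq(k) * h2[k + 1L] * (bigq(1) - h02))
    rows[[length(rows) + 1L]] <- row
    rhs[[length(rhs) + 1L]] <- b
  }

  m <- length(rows)
  if (m < nu) {
    stop("underdetermined elimination (", m, " equations for ", nu,
         " unknowns): fix more values", call. = FALSE)
  }
  leftover <- list()
  if (m > nu) {
    extra <- (nu + 1L):m
    leftover_rows <- rows[extra]; leftover_rhs <- rhs[extra]
    rows <- rows[seq_len(nu)]; rhs <- rhs[seq_len(nu)]
  } else {
    leftover_rows <- list(); leftover_rhs <- list()
  }
  u <- solve_affine_system(rows, rhs)
  if (is.null(u)) return(list())

  # leftover linear equations become root constraints on x
  constraints <- list()
  for (j in seq_along(leftover_rows)) {
    e <- -leftover_rhs[[j]]
    for (i in seq_len(nu)) e <- e + leftover_rows[[j]][[i]] * u[[i]]
    constraints[[length(constraints) + 1L]] <- e$num
  }

  # l=1 coupling equations: P_k(x) + K31 Q_k(x) = 0 after multiplying by
  # (1 - h01) = (1 - x), with u_k = h_k1(x):
  # P_k = h_k2 (1-x) + (h02 - 1) u_k + x - h02
  # Q_k = -n u_k + n x + k u_k (1-x)
  P <- list(); Q <- list()
  one_minus_x <- as_qrf(1) - x
  for (k in k93) {
    ik <- match(k, k93)
    uk <- u[[ik]]
    P[[length(P) + 1L]] <- as_qrf(h2[k + 1L]) * one_minus_x +
      as_qrf(h02 - bigq(1)) * uk + x - as_qrf(h02)
    Q[[length(Q) + 1L]] <- as_qrf(-nn) * uk + as_qrf(nn) * x +
      as_qrf(bigq(k)) * uk * one_minus_x
  }
  if (length(P) >= 2L) {
    for (j in 2:length(P)) {
      e <- P[[j]] * Q[[1L]] - P[[1L]] * Q[[j]]
      constraints[[length(constraints) + 1L]] <- e$num
    }
  }
  constraints <- Filter(function(pp) !qp_is_zero(pp), constraints)
  if (length(constraints) == 0L) {
    stop("free constraint system left h01 undetermined: an infinite branch ",
         "family exists for these choices", call. = FALSE)
  }
  cands <- qp_rational_roots(constraints[[1L]])
  for (pp in constraints[-1L]) {
    keep <- vapply(seq_along(cands), function(i) {
      bq_is_zero(qp_eval(pp, cands[i]))
    }, logical(1))
    cands <- cands[keep]
  }

  branches <- list()
  for (i in seq_along(cands)) {
    x0 <- cands[i]
    br <- tryCatch({
      h1 <- rep(bigq("0"), n)
      h1[1L] <- x0
      for (k in k93) h1[k + 1L] <- qrf_eval(u[[match(k, k93)]], x0)
      K32 <- qrf_eval(u[[nu]], x0)
      q1v <- qrf_eval(Q[[1L]], x0)
      if (bq_is_zero(q1v)) stop("K31 undetermined at this root")
      K31 <- -qrf_eval(P[[1L]], x0) / q1v
      K3 <- c(K31, K32)
      if (any(bq_is_zero(K3))) stop("zero K3 branch")
      h <- list(h1, h2)
      rep <- constraint_residuals(n, A$A1, K3, h, zero_aes)
      if (!rep$pass) stop("branch failed exact verification")
      list(A1 = A$A1, h = h, K3 = K3, report = rep)
    }, error = function(e) NULL)
    if (!is.null(br)) branches[[length(branches) + 1L]] <- br
  }
  branches
}

#' Model coefficients from auxiliary parameters
#'
#' Applies the coefficient map
#' \deqn{a_{0l} = -\eta \sigma_{1l}/A_{2l}, \quad
#'       a_{1l} = \eta (N_{1l} - A_{1l}/A_{2l}), \quad
#'       a_{2l} = N_{2l}\eta/\sigma_{1l}, \quad
#'       \lambda_l = N_{3l}\eta/\sigma_{2l},}
#' \deqn{b_{0l} = -\eta\sigma_{2l} K_{2l}/K_{3l}, \quad
#'       b_{2l} = L_{3l}\eta/\sigma_{2l}, \quad
#'       \mu_l = L_{2l}\eta/\sigma_{1l}, \quad
#'       \gamma_l = -\eta\sigma_{2l}/(K_{3l}\sigma_{2r}),}
#' and, by default, the re-derived linear-term map
#' \deqn{b_{1l} = \eta\bigl(L_{1l} - K_{1l}/K_{3l}
#'       - \sigma_{2l}/(K_{3l}\sigma_{2r})\bigr),}
#' which is the variant consistent with the defining relations of the
#' auxiliary parameters. The algebraically inequivalent variant
#' \eqn{b_{1l} = -\eta(K_{1l}/K_{3l} + \sigma_{2l}/(K_{3l}\sigma_{2r})
#' + L_{1l})} (sign of the \eqn{L_{1l}} term flipped) is available as
#' `b1_formula = "flipped_L1"` for regression comparison only; it does not
#' produce systems solved by the assembled solutions.
#'
#' @param aux an [lv_aux].
#' @param sigmas length-4 exact vector
#'   \eqn{(\sigma_{11}, \sigma_{21}, \sigma_{12}, \sigma_{22})}, all
#'   nonzero.
#' @param eta exact nonzero rate.
#' @param b1_formula `"rederived"` (default) or `"flipped_L1"`.
#' @return an [lv_system]; every coefficient scales linearly with `eta`.
#' @export
assemble_system <- function(aux, sigmas, eta,
                            b1_formula = c("rederived", "flipped_L1")) {
  b1_formula <- match.arg(b1_formula)
  sigmas <- bigq(sigmas); eta <- bigq(eta)
  if (length(sigmas) != 4L) stop("sigmas must have length 4", call. = FALSE)
  if (any(bq_is_zero(sigmas))) stop("all sigmas must be nonzero",
                                    call. = FALSE)
  if (bq_is_zero(eta)) stop("eta must be nonzero", call. = FALSE)
  s1 <- sigmas[c(1L, 3L)]   # sigma_1l: amplitudes of x1, x2
  s2 <- sigmas[c(2L, 4L)]   # sigma_2l: amplitudes of y1, y2
  z <- bigq(c(0, 0))
  a0 <- a1 <- a2 <- lam <- b0 <- b1 <- b2 <- mu <- gam <- z
  for (l in 1:2) {
    r <- 3L - l
    a0[l] <- -eta * s1[l] / aux$A2[l]
    a1[l] <- eta * (aux$N1[l] - aux$A1[l] / aux$A2[l])
    a2[l] <- aux$N2[l] * eta / s1[l]
    lam[l] <- aux$N3[l] * eta / s2[l]
    b0[l] <- -eta * s2[l] * aux$K2[l] / aux$K3[l]
    b2[l] <- aux$L3[l] * eta / s2[l]
    mu[l] <- aux$L2[l] * eta / s1[l]
    gam[l] <- -eta * s2[l] / (aux$K3[l] * s2[r])
    b1[l] <- if (b1_formula == "rederived") {
      eta * (aux$L1[l] - aux$K1[l] / aux$K3[l] - s2[l] / (aux$K3[l] * s2[r]))
    } else {
      -eta * (aux$K1[l] / aux$K3[l] + s2[l] / (aux$K3[l] * s2[r]) + aux$L1[l])
    }
  }
  lv_system(a0, a1, a2, lam, b0, b1, b2, mu, gam)
}

#' Construct a complete (auxiliaries, solution, system) triple
#'
#' Runs the full forward pipeline for a requested order: solves the
#' condition system from the free choices ([solve_free_constraints()]),
#' builds the auxiliary set, assembles the solitary solution from the p/h
#' ratio tables, and maps the auxiliaries to model coefficients. The
#' resulting triple satisfies all balancing identities exactly (verifiable
#' with [residual_identities()] and [ode_residual()]).
#'
#' For `n = 1` the free choices additionally carry `L31`, `L32`, `N31`,
#' `N32` (the L and N triples are independent only at order 1).
#'
#' @param n order.
#' @param fixed named list of free choices (schema of
#'   [solve_free_constraints()], plus the order-1 extras).
#' @param aes length-`n` exact vector of shared denominator coefficients;
#'   entries at `zero_aes` indices must be zero.
#' @param sigmas length-4 exact vector of amplitudes.
#' @param eta,t0 exact rate (nonzero) and time shift.
#' @param zero_aes zeroed indices (default \eqn{2, \dots, n-2} for
#'   \eqn{n > 3}).
#' @param branch which solution branch to take when several exist.
#' @return a list with `aux` ([lv_aux]), `solution` ([lv_solution]),
#'   `system` ([lv_system]), and `n_branches`.
#' @export
assemble_full <- function(n, fixed, aes, sigmas, eta, t0,
                          zero_aes = NULL, branch = 1L) {
  n <- as.integer(n)
  if (is.null(zero_aes)) zero_aes <- default_zero_aes(n)
  zero_aes <- check_zero_aes(n, zero_aes)
  aes <- bigq(aes)
  if (length(aes) != n) stop("aes must have length n", call. = FALSE)
  if (length(zero_aes) > 0L && !all(bq_is_zero(aes[zero_aes + 1L]))) {
    stop("aes entries at the zeroed indices (", paste(zero_aes, collapse = ", "),
         ") must be zero", call. = FALSE)
  }
  branches <- solve_free_constraints(n, fixed, zero_aes)
  if (length(branches) == 0L) {
    stop("the condition system has no exact solution branch for these ",
         "choices", call. = FALSE)
  }
  if (branch > length(branches)) {
    stop("requested branch ", branch, " but only ", length(branches),
         " exist", call. = FALSE)
  }
  br <- branches[[branch]]
  A <- solve_A(n, br$A1)
  if (n == 1L) {
    for (nm in c("L31", "L32", "N31", "N32")) {
      if (is.null(fixed[[nm]])) {
        stop("order 1 requires free choice ", nm, call. = FALSE)
      }
    }
    L3 <- bigq(c(fixed$L31, fixed$L32))
    N3 <- bigq(c(fixed$N31, fixed$N32))
    L12 <- lapply(1:2, function(l) {
      solve_LN_order1(A$p[[l]][1], br$h[[l]][1], L3[l])
    })
    N12 <- lapply(1:2, function(l) {
      solve_LN_order1(A$p[[l]][1], br$h[[l]][1], N3[l])
    })
    L1 <- c(L12[[1]][1], L12[[2]][1]); L2 <- c(L12[[1]][2], L12[[2]][2])
    N1 <- c(N12[[1]][1], N12[[2]][1]); N2 <- c(N12[[1]][2], N12[[2]][2])
  } else {
    Ltri <- lapply(1:2, function(l) {
      solve_LN_unique(n, A$p[[l]][1], A$p[[l]][2], br$h[[l]][1], br$h[[l]][2])
    })
    L1 <- N1 <- c(Ltri[[1]][1], Ltri[[2]][1])
    L2 <- N2 <- c(Ltri[[1]][2], Ltri[[2]][2])
    L3 <- N3 <- c(Ltri[[1]][3], Ltri[[2]][3])
  }
  K12 <- lapply(1:2, function(l) {
    r <- 3L - l
    solve_K(n, br$h[[l]][1], br$h[[r]][1], br$K3[l])
  })
  aux <- lv_aux(n, br$A1,
                L1 = L1, L2 = L2, L3 = L3,
                N1 = N1, N2 = N2, N3 = N3,
                K1 = c(K12[[1]][1], K12[[2]][1]),
                K2 = c(K12[[1]][2], K12[[2]][2]),
                K3 = br$K3)
  sol <- lv_solution(n, eta, t0, sigmas, aes,
                     list(x1 = A$p[[1L]], y1 = br$h[[1L]],
                          x2 = A$p[[2L]], y2 = br$h[[2L]]))
  sys <- assemble_system(aux, sigmas, eta)
  list(aux = aux, solution = sol, system = sys, n_branches = length(branches))
}
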