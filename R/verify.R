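#' Symbolic balancing identities of a (system, solution, auxiliaries) triple
#'
#' Expands the eight polynomial identities in \eqn{\hat t} that are
#' necessary and sufficient for the closed-form components to solve the
#' model: per subsystem \eqn{l}, with \eqn{\alpha_l = -\eta A_{1l}/A_{2l}},
#' \eqn{\beta_l = \eta L_{1l}} and \eqn{c_l = b_{1l} - \gamma_l},
#' \deqn{a_{0l} T + \alpha_l \sigma_{1l} X_l - \eta \hat t \sigma_{1l} X_l' = 0,}
#' \deqn{\eta \hat t T' + (a_{1l} - \alpha_l) T + a_{2l} \sigma_{1l} X_l
#'       + \lambda_l \sigma_{2l} Y_l = 0,}
#' \deqn{\eta \hat t T' + \beta_l T + \mu_l \sigma_{1l} X_l
#'       + b_{2l} \sigma_{2l} Y_l = 0,}
#' \deqn{\gamma_l \sigma_{2r} Y_r + (c_l - \beta_l) \sigma_{2l} Y_l
#'       + b_{0l} T - \eta \sigma_{2l} \hat t Y_l' = 0.}
#' Each residual is the exact coefficient vector of the reduced polynomial;
#' the triple passes iff all eight are the zero polynomial.
#'
#' @param sys an [lv_system].
#' @param sol an [lv_solution].
#' @param aux an [lv_aux] supplying \eqn{A} and \eqn{L_1} (which enter
#'   through \eqn{\alpha_l} and \eqn{\beta_l}).
#' @return a [condition_report] with residuals named
#'   `x_const_l<l>`, `x_linear_l<l>`, `y_linear_l<l>`, `y_const_l<l>`.
#' @export
residual_identities <- function(sys, sol, aux) {
  eta <- sol$eta
  s1 <- sol$sigmas[c(1L, 3L)]
  s2 <- sol$sigmas[c(2L, 4L)]
  Tden <- sol$components$x1$den
  X <- list(sol$components$x1$num, sol$components$x2$num)
  Y <- list(sol$components$y1$num, sol$components$y2$num)
  dT <- qp_that_deriv(Tden)
  res <- list()
  for (l in 1:2) {
    r <- 3L - l
    alpha <- -eta * aux$A1[l] / aux$A2[l]
    beta <- eta * aux$L1[l]
    cl <- sys$b1[l] - sys$gamma[l]
    res[[paste0("x_const_l", l)]] <- qp_add(
      qp_add(qp_scale(Tden, sys$a0[l]), qp_scale(X[[l]], alpha * s1[l])),
      qp_scale(qp_that_deriv(X[[l]]), -eta * s1[l])
    )$coef
    res[[paste0("x_linear_l", l)]] <- qp_add(
      qp_add(qp_scale(dT, eta), qp_scale(Tden, sys$a1[l] - alpha)),
      qp_add(qp_scale(X[[l]], sys$a2[l] * s1[l]),
             qp_scale(Y[[l]], sys$lambda[l] * s2[l]))
    )$coef
    res[[paste0("y_linear_l", l)]] <- qp_add(
      qp_add(qp_scale(dT, eta), qp_scale(Tden, beta)),
      qp_add(qp_scale(X[[l]], sys$mu[l] * s1[l]),
             qp_scale(Y[[l]], sys$b2[l] * s2[l]))
    )$coef
    res[[paste0("y_const_l", l)]] <- qp_add(
      qp_add(qp_scale(Y[[r]], sys$gamma[l] * s2[r]),
             qp_scale(Y[[l]], (cl - beta) * s2[l])),
      qp_add(qp_scale(Tden, sys$b0[l]),
             qp_scale(qp_that_deriv(Y[[l]]), -eta * s2[l]))
    )$coef
  }
  condition_report(res)
}

#' Exact residual of the model equations under a closed-form solution
#'
#' Substitutes the solution into the four model equations directly and
#' reduces each residual to a polynomial in \eqn{\hat t}. Writing
#' \eqn{x_l = \sigma_{1l} X_l / T} and using
#' \eqn{\mathrm{d}\hat t/\mathrm{d}t = \eta\hat t}, the x-equation residual
#' multiplied through by \eqn{T^2} reads
#' \deqn{\eta \sigma_{1l} \hat t (X_l' T - X_l T')
#'   - a_{0l} T^2 - a_{1l} \sigma_{1l} X_l T - a_{2l} \sigma_{1l}^2 X_l^2
#'   - \lambda_l \sigma_{1l} \sigma_{2l} X_l Y_l,}
#' and analogously for the y-equation with its diffusive term
#' \eqn{-\gamma_l (\sigma_{2r} Y_r - \sigma_{2l} Y_l) T}. The pair solves
#' the system identically iff all four residual polynomials vanish. Unlike
#' [residual_identities()] this oracle needs no auxiliary parameters.
#'
#' @param sys an [lv_system].
#' @param sol an [lv_solution].
#' @return a [condition_report] with residuals named `x_l1`, `y_l1`,
#'   `x_l2`, `y_l2` (exact coefficient vectors).
#' @export
ode_residual <- function(sys, sol) {
  eta <- sol$eta
  s1 <- sol$sigmas[c(1L, 3L)]
  s2 <- sol$sigmas[c(2L, 4L)]
  Tden <- sol$components$x1$den
  X <- list(sol$components$x1$num, sol$components$x2$num)
  Y <- list(sol$components$y1$num, sol$components$y2$num)
  dT <- qp_that_deriv(Tden)
  res <- list()
  for (l in 1:2) {
    r <- 3L - l
    dX <- qp_that_deriv(X[[l]])
    dY <- qp_that_deriv(Y[[l]])
    rx <- qp_scale(qp_sub(qp_mul(dX, Tden), qp_mul(X[[l]], dT)), eta * s1[l])
    rx <- qp_sub(rx, qp_scale(qp_mul(Tden, Tden), sys$a0[l]))
    rx <- qp_sub(rx, qp_scale(qp_mul(X[[l]], Tden), sys$a1[l] * s1[l]))
    rx <- qp_sub(rx, qp_scale(qp_mul(X[[l]], X[[l]]),
                              sys$a2[l] * s1[l] * s1[l]))
    rx <- qp_sub(rx, qp_scale(qp_mul(X[[l]], Y[[l]]),
                              sys$lambda[l] * s1[l] * s2[l]))
    ry <- qp_scale(qp_sub(qp_mul(dY, Tden), qp_mul(Y[[l]], dT)), eta * s2[l])
    ry <- qp_sub(ry, qp_scale(qp_mul(Tden, Tden), sys$b0[l]))
    ry <- qp_sub(ry, qp_scale(qp_mul(Y[[l]], Tden), sys$b1[l] * s2[l]))
    ry <- qp_sub(ry, qp_scale(qp_mul(Y[[l]], Y[[l]]),
                              sys$b2[l] * s2[l] * s2[l]))
    ry <- qp_sub(ry, qp_scale(qp_mul(X[[l]], Y[[l]]),
                              sys$mu[l] * s1[l] * s2[l]))
    ry <- qp_sub(ry, qp_scale(
      qp_mul(qp_sub(qp_scale(Y[[r]], s2[r]), qp_scale(Y[[l]], s2[l])), Tden),
      sys$gamma[l]))
    res[[paste0("x_l", l)]] <- rx$coef
    res[[paste0("y_l", l)]] <- ry$coef
  }
  condition_report(res)
}

#' Numerical integration cross-check of a closed-form solution
#'
#' Integrates the model numerically from the closed form's value at the
#' start of the window and reports the maximum pointwise deviation between
#' the trajectory and the closed form on a uniform grid. This is a
#' redundancy check: the symbolic residuals are the authority, and a small
#' deviation here confirms that the exact algebra and the floating-point
#' evaluation agree.
#'
#' @param sys an [lv_system].
#' @param sol an [lv_solution].
#' @param t_span length-2 numeric window; must not contain a pole of the
#'   shared denominator (error naming the pole time otherwise).
#' @param rtol integrator relative tolerance (also used as `atol`).
#' @param n_grid number of grid points.
#' @return the maximum absolute deviation over all grid points and
#'   components (a single numeric).
#' @export
integrate_and_compare <- function(sys, sol, t_span, rtol = 1e-10,
                                  n_grid = 200L) {
  stopifnot(length(t_span) == 2L, t_span[2] > t_span[1])
  poles <- pole_times(sol)
  inside <- poles[poles >= t_span[1] & poles <= t_span[2]]
  if (length(inside) > 0L) {
    stop("solution has a pole at t = ", signif(inside[1L], 10),
         " inside the integration window", call. = FALSE)
  }
  grid <- seq(t_span[1], t_span[2], length.out = n_grid)
  exact <- evaluate_solution(sol, grid)
  co <- lapply(sys, as.numeric)
  deriv <- function(t, state, parms) {
    x <- state[c(1L, 3L)]
    y <- state[c(2L, 4L)]
    dx <- co$a0 + co$a1 * x + co$a2 * x^2 + co$lambda * x * y
    dy <- co$b0 + co$b1 * y + co$b2 * y^2 + co$mu * x * y +
      co$gamma * (rev(y) - y)
    list(c(dx[1], dy[1], dx[2], dy[2]))
  }
  y0 <- as.numeric(exact[1L, c("x1", "y1", "x2", "y2")])
  traj <- deSolve::ode(y = y0, times = grid, func = deriv, parms = NULL,
                       rtol = rtol, atol = rtol)
  max(abs(as.matrix(traj[, 2:5]) -
            as.matrix(exact[, c("x1", "y1", "x2", "y2")])))
}

#' Seeded generator of valid random fixtures
#'
#' Draws small random rationals for every free choice of the forward
#' constructor, completes them to a full (auxiliaries, solution, system)
#' triple, and certifies the result exactly. Draws violating a guard, or
#' free choices for which the condition system has no exact branch, are
#' redrawn (bounded retries). Deterministic per seed; the caller's random
#' number generator state is left untouched.
#'
#' @param n order.
#' @param seed integer seed.
#' @param ranges list of draw bounds: `max_abs` bounds numerator magnitude
#'   and denominator of every drawn rational (default 12), `max_tries` the
#'   retry budget (default 400).
#' @return a list of class `lv_fixture` with `n`, `seed`, `fixed`, `aes`,
#'   `sigmas`, `eta`, `t0`, `zero_aes`, and the certified `aux`,
#'   `solution`, `system`.
#' @export
generate_fixture <- function(n, seed, ranges = list()) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  max_abs <- if (is.null(ranges$max_abs)) 12L else as.integer(ranges$max_abs)
  max_tries <- if (is.null(ranges$max_tries)) 400L
               else as.integer(ranges$max_tries)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)

  draw <- function(nonzero = FALSE) {
    repeat {
      p <- sample(seq.int(-max_abs, max_abs), 1L)
      if (nonzero && p == 0L) next
      q <- sample(seq_len(max_abs), 1L)
      return(bigq(p) / bigq(q))
    }
  }
  zero_aes <- default_zero_aes(n)

  for (try in seq_len(max_tries)) {
    fix <- tryCatch({
      fixed <- list(A11 = draw(nonzero = TRUE), A12 = draw(nonzero = TRUE))
      if (n == 1L) {
        fixed <- c(fixed, list(h01 = draw(), h02 = draw(),
                               K31 = draw(nonzero = TRUE),
                               K32 = draw(nonzero = TRUE),
                               L31 = draw(nonzero = TRUE),
                               L32 = draw(nonzero = TRUE),
                               N31 = draw(nonzero = TRUE),
                               N32 = draw(nonzero = TRUE)))
      } else if (n == 2L) {
        fixed <- c(fixed, list(h01 = draw(), h02 = draw(),
                               h11 = draw(), h12 = draw()))
      } else {
        for (k in active_indices(n, zero_aes, 1L)) {
          fixed[[paste0("h", k, "2")]] <- draw()
        }
      }
      aes <- rep(bigq("0"), n)
      aes[1L] <- draw(nonzero = TRUE)
      for (k in setdiff(seq_len(n - 1L), zero_aes)) {
        aes[k + 1L] <- draw(nonzero = TRUE)
      }
      sigmas <- c(draw(nonzero = TRUE), draw(nonzero = TRUE),
                  draw(nonzero = TRUE), draw(nonzero = TRUE))
      eta <- draw(nonzero = TRUE)
      t0 <- draw()
      triple <- assemble_full(n, fixed, aes, sigmas, eta, t0, zero_aes)
      if (!residual_identities(triple$system, triple$solution,
                               triple$aux)$pass ||
          !ode_residual(triple$system, triple$solution)$pass) {
        stop("fixture failed exact certification")
      }
      structure(
        list(n = n, seed = seed, fixed = fixed, aes = aes, sigmas = sigmas,
             eta = eta, t0 = t0, zero_aes = zero_aes,
             aux = triple$aux, solution = triple$solution,
             system = triple$system),
        class = "lv_fixture")
    }, error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fix)) return(fix)
  }
  stop("fixture retry budget (", max_tries, ") exhausted for n = ", n,
       call. = FALSE)
}

#' @export
print.lv_fixture <- function(x, ...) {
  cat("<lv_fixture> order ", x$n, ", seed ", x$seed, ", eta = ",
      unclass(x$eta), "\n", sep = "")
  print(x$system)
  invisible(x)
}
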