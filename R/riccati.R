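#' Single Riccati equation
#'
#' Represents \eqn{x' = c_0 + c_1 x + c_2 x^2} with exact rational
#' coefficients. This is the order-1 base case of the solitary-solution
#' hierarchy: its bounded solutions are kinks, monotone transitions between
#' the two equilibria.
#'
#' @param c0,c1,c2 exact rational coefficients; `c2` must be nonzero.
#' @return an object of class `lv_riccati`.
#' @examples
#' lv_riccati("-1", "5", "-4")
#' @export
lv_riccati <- function(c0, c1, c2) {
  c0 <- bigq(c0); c1 <- bigq(c1); c2 <- bigq(c2)
  if (bq_is_zero(c2)) stop("c2 must be nonzero (equation is not Riccati)",
                           call. = FALSE)
  structure(list(c0 = c0, c1 = c1, c2 = c2), class = "lv_riccati")
}

#' @export
print.lv_riccati <- function(x, ...) {
  cat("<lv_riccati> x' = ", unclass(x$c0), " + ", unclass(x$c1), " x + ",
      unclass(x$c2), " x^2\n", sep = "")
  invisible(x)
}

#' Decay rate of a Riccati equation
#'
#' The kink decay rate satisfies \eqn{\eta^2 = c_1^2 - 4 c_0 c_2}. The
#' squared value is always exact; the principal (nonnegative) root is exact
#' when the square is a perfect rational square, numeric otherwise, and
#' flagged complex when \eqn{\eta^2 < 0} (no real kink exists).
#'
#' @param eq an [lv_riccati].
#' @return a list with `eta_squared` ([bigq]), `real` (logical), `eta`
#'   ([bigq] exact root or `NA` if irrational/complex), and `eta_num`
#'   (double; `NA` if complex).
#' @examples
#' riccati_eta(lv_riccati("-1", "5", "-4"))$eta  # exactly 3
#' @export
riccati_eta <- function(eq) {
  e2 <- eq$c1^2 - bigq(4) * eq$c0 * eq$c2
  if (bq_sign(e2) < 0L) {
    return(list(eta_squared = e2, real = FALSE,
                eta = new_bigq(NA_character_), eta_num = NA_real_))
  }
  list(eta_squared = e2, real = TRUE, eta = bq_sqrt(e2),
       eta_num = sqrt(as.numeric(e2)))
}

#' Kink solitary solution of a Riccati equation
#'
#' Represents \eqn{x(t) = \sigma \frac{e^{\eta t} - s x_0}{e^{\eta t} - s t_0}}.
#' The pair \eqn{(x_0, t_0)} is only determined up to common scaling (the
#' free constant `s` absorbs the scale), so constructors may normalize
#' \eqn{t_0 = 1}.
#'
#' @param sigma amplitude \eqn{\sigma} (the \eqn{t \to +\infty} limit for
#'   \eqn{\eta > 0}).
#' @param x0_root,t0_root the numerator/denominator root parameters
#'   \eqn{x_0 \neq t_0}.
#' @param s free constant fixed by the initial condition.
#' @param eta exact nonzero decay rate.
#' @return an object of class `lv_kink`.
#' @export
lv_kink <- function(sigma, x0_root, t0_root, s, eta) {
  sigma <- bigq(sigma); x0_root <- bigq(x0_root); t0_root <- bigq(t0_root)
  s <- bigq(s); eta <- bigq(eta)
  if (x0_root == t0_root) stop("x0_root must differ from t0_root",
                               call. = FALSE)
  if (bq_is_zero(eta)) stop("eta must be nonzero", call. = FALSE)
  structure(list(sigma = sigma, x0_root = x0_root, t0_root = t0_root,
                 s = s, eta = eta),
            class = "lv_kink")
}

#' @export
print.lv_kink <- function(x, ...) {
  cat("<lv_kink> sigma = ", unclass(x$sigma), ", x0 = ", unclass(x$x0_root),
      ", t0 = ", unclass(x$t0_root), ", s = ", unclass(x$s),
      ", eta = ", unclass(x$eta), "\n", sep = "")
  invisible(x)
}

#' Riccati coefficients generated by a kink solution
#'
#' Applies the defining identities
#' \deqn{c_0 = \frac{\sigma x_0 \eta}{x_0 - t_0}, \quad
#'       c_1 = \frac{(t_0 + x_0)\eta}{t_0 - x_0}, \quad
#'       c_2 = \frac{t_0 \eta}{\sigma (x_0 - t_0)}.}
#' The output always satisfies \eqn{c_1^2 - 4 c_0 c_2 = \eta^2} identically.
#'
#' @param sol an [lv_kink]; `sigma` must be nonzero (else \eqn{c_2} is
#'   undefined).
#' @return an [lv_riccati].
#' @examples
#' kink_coeffs(lv_kink(1, 1, 2, 1, 1))  # x' = -1 + 3 x - 2 x^2
#' @export
kink_coeffs <- function(sol) {
  if (bq_is_zero(sol$sigma)) {
    stop("sigma = 0 is a degenerate amplitude: c2 is undefined", call. = FALSE)
  }
  d <- sol$x0_root - sol$t0_root
  lv_riccati(
    c0 = sol$sigma * sol$x0_root * sol$eta / d,
    c1 = -(sol$t0_root + sol$x0_root) * sol$eta / d,
    c2 = sol$t0_root * sol$eta / (sol$sigma * d)
  )
}

#' Kink solution of a Riccati equation through an initial point
#'
#' Inverts the coefficient identities: with \eqn{\eta > 0} the principal
#' root of \eqn{c_1^2 - 4 c_0 c_2}, the gauge \eqn{t_0 = 1} gives
#' \eqn{x_0 = (c_1 - \eta)/(c_1 + \eta)} and
#' \eqn{\sigma = -(c_1 + \eta)/(2 c_2)} (the equilibrium approached as
#' \eqn{t \to +\infty}); the sign of \eqn{\eta} is flipped if
#' \eqn{c_1 + \eta = 0}. The free constant follows from the initial value:
#' \eqn{s = (\sigma - x_{init})/(\sigma x_0 - x_{init})} at \eqn{t = 0}.
#'
#' @param eq an [lv_riccati] with real, nonzero, rational decay rate (the
#'   discriminant must be a positive perfect rational square; irrational
#'   rates admit no exact kink in this representation).
#' @param x_init exact initial value \eqn{x(0)}. An equilibrium value
#'   returns the constant solution (`s = 0` branch or flagged constant).
#' @return a list with `solution` (an [lv_kink], or `NULL` for the constant
#'   case), `constant` (the [bigq] equilibrium when degenerate, else `NA`),
#'   and `pole_time` (double; finite-time pole location if `s > 0`, else
#'   `NA`).
#' @examples
#' k <- kink_from_coeffs(lv_riccati("-1", "5", "-4"), "1/3")
#' k$solution
#' @export
kink_from_coeffs <- function(eq, x_init) {
  x_init <- bigq(x_init)
  et <- riccati_eta(eq)
  if (!et$real) stop("complex decay rate: no real kink solution", call. = FALSE)
  if (bq_is_zero(et$eta_squared)) {
    stop("zero decay rate: equilibria coincide, no kink", call. = FALSE)
  }
  if (is.na(unclass(et$eta))) {
    stop("decay rate is irrational; exact kink construction requires a ",
         "rational rate", call. = FALSE)
  }
  eta <- et$eta
  if (bq_is_zero(eq$c1 + eta)) eta <- -eta
  sigma <- -(eq$c1 + eta) / (bigq(2) * eq$c2)
  x0 <- (eq$c1 - eta) / (eq$c1 + eta)
  other <- sigma * x0  # the t -> -infty equilibrium (t0 gauge-fixed to 1)
  if (x_init == sigma) {
    return(list(solution = lv_kink(sigma, x0, bigq(1), bigq(0), eta),
                constant = sigma, pole_time = NA_real_))
  }
  if (x_init == other) {
    return(list(solution = NULL, constant = other, pole_time = NA_real_))
  }
  s <- (sigma - x_init) / (other - x_init)
  pole <- if (bq_sign(s) > 0L) log(as.numeric(s)) / as.numeric(eta)
          else NA_real_
  list(solution = lv_kink(sigma, x0, bigq(1), s, eta),
       constant = new_bigq(NA_character_), pole_time = pole)
}

#' Symbolic residual of a kink against a Riccati equation
#'
#' Expands \eqn{(x' - c_0 - c_1 x - c_2 x^2)(\hat t - s t_0)^2} as an exact
#' polynomial in \eqn{\hat t = e^{\eta t}}; the kink solves the equation iff
#' this polynomial is identically zero.
#'
#' @param sol an [lv_kink].
#' @param eq an [lv_riccati].
#' @return a [condition_report] with the residual polynomial coefficients.
#' @export
kink_residual <- function(sol, eq) {
  num <- qpoly(c(-sol$s * sol$x0_root, bigq(1)))   # that - s*x0
  den <- qpoly(c(-sol$s * sol$t0_root, bigq(1)))   # that - s*t0
  # x' = eta * that * sigma * s * (x0 - t0) / den^2
  dnum <- qp_scale(qpoly(c(bigq(0), bigq(1))),
                   sol$eta * sol$sigma * sol$s * (sol$x0_root - sol$t0_root))
  res <- qp_sub(dnum, qp_scale(qp_mul(den, den), eq$c0))
  res <- qp_sub(res, qp_scale(qp_mul(num, den), eq$c1 * sol$sigma))
  res <- qp_sub(res, qp_scale(qp_mul(num, num), eq$c2 * sol$sigma^2))
  condition_report(list(kink_ode_residual = res$coef))
}

#' Evaluate a kink solution on a time grid
#'
#' @param sol an [lv_kink].
#' @param t numeric vector of times.
#' @return numeric vector of \eqn{x(t)} values.
#' @export
kink_evaluate <- function(sol, t) {
  that <- exp(as.numeric(sol$eta) * t)
  s <- as.numeric(sol$s)
  as.numeric(sol$sigma) * (that - s * as.numeric(sol$x0_root)) /
    (that - s * as.numeric(sol$t0_root))
}

# ---------------------------------------------------------------------------
# multiplicatively coupled Riccati pair

#' Multiplicatively coupled Riccati pair
#'
#' Represents the system
#' \deqn{x' = a_0 + a_1 x + a_2 x^2 + a_3 x y, \qquad
#'       y' = b_0 + b_1 y + b_2 y^2 + b_3 x y.}
#' This is the building block coupled diffusively in the four-equation
#' model; on its own it admits dark/bright solitary solutions when the
#' existence conditions checked by [pair_existence_check()] hold.
#'
#' @param a,b length-4 exact vectors \eqn{(a_0, a_1, a_2, a_3)} and
#'   \eqn{(b_0, b_1, b_2, b_3)}.
#' @return an object of class `lv_pair`.
#' @export
lv_pair <- function(a, b) {
  a <- bigq(a); b <- bigq(b)
  if (length(a) != 4L || length(b) != 4L) {
    stop("a and b must each have length 4", call. = FALSE)
  }
  structure(list(a = a, b = b), class = "lv_pair")
}

#' @export
print.lv_pair <- function(x, ...) {
  a <- unclass(x$a); b <- unclass(x$b)
  cat("<lv_pair>\n  x' = ", a[1], " + ", a[2], " x + ", a[3], " x^2 + ",
      a[4], " x y\n  y' = ", b[1], " + ", b[2], " y + ", b[3], " y^2 + ",
      b[4], " x y\n", sep = "")
  invisible(x)
}

#' Existence conditions for dark/bright solutions of a coupled pair
#'
#' Checks the three exact conditions: the cross-coupling symmetries
#' \eqn{a_3 = b_2} and \eqn{a_2 = b_3}, and the cubic compatibility
#' condition
#' \deqn{9 a_0 a_1 a_2 + 9 b_0 b_1 b_2 - 18 a_0 a_2 b_1 - 18 b_0 b_2 a_1
#'       + 3 a_1 b_1^2 + 3 b_1 a_1^2 - 2 a_1^3 - 2 b_1^3 = 0,}
#' evaluated exactly as a single polynomial expression.
#'
#' @param sys an [lv_pair].
#' @return a [condition_report] with residuals `a3_minus_b2`,
#'   `a2_minus_b3`, `cubic_condition`.
#' @export
pair_existence_check <- function(sys) {
  a <- sys$a; b <- sys$b
  cubic <- bigq(9) * a[1] * a[2] * a[3] + bigq(9) * b[1] * b[2] * b[3] -
    bigq(18) * a[1] * a[3] * b[2] - bigq(18) * b[1] * b[3] * a[2] +
    bigq(3) * a[2] * b[2]^2 + bigq(3) * b[2] * a[2]^2 -
    bigq(2) * a[2]^3 - bigq(2) * b[2]^3
  condition_report(list(
    a3_minus_b2 = a[4] - b[3],
    a2_minus_b3 = a[3] - b[4],
    cubic_condition = cubic
  ))
}

#' Decay rate of a coupled pair system
#'
#' Evaluates, exactly,
#' \deqn{\eta = \frac{a_1^2 - a_1 b_1 + b_1^2}{3} - a_0 a_2 - b_0 b_2.}
#'
#' @param sys an [lv_pair].
#' @return a length-one [bigq].
#' @export
pair_eta <- function(sys) {
  a <- sys$a; b <- sys$b
  (a[2]^2 - a[2] * b[2] + b[2]^2) / bigq(3) - a[1] * a[3] - b[1] * b[3]
}

#' Root-parameter constraints of dark/bright solutions
#'
#' Checks the two exact relations
#' \deqn{\frac{(\bar x_1 - \bar t_1)(\bar x_1 - \bar t_2)}
#'            {(\bar x_2 - \bar t_1)(\bar x_2 - \bar t_2)}
#'       = -\frac{\bar x_1}{\bar x_2}}
#' (and its \eqn{\bar y} analogue), in cross-multiplied form so that no
#' division is performed on the residual itself.
#'
#' @param xbar,ybar,tbar length-2 exact vectors of the numerator roots of
#'   x, of y, and of the shared denominator.
#' @return a [condition_report] with residuals `x_relation`, `y_relation`.
#' @export
pair_root_constraints <- function(xbar, ybar, tbar) {
  xbar <- bigq(xbar); ybar <- bigq(ybar); tbar <- bigq(tbar)
  stopifnot(length(xbar) == 2L, length(ybar) == 2L, length(tbar) == 2L)
  guards <- character(0)
  if (bq_is_zero(xbar[2])) guards <- c(guards, "xbar2_zero")
  if (bq_is_zero(ybar[2])) guards <- c(guards, "ybar2_zero")
  if (length(guards) > 0L) {
    stop("zero denominator root parameter: ", paste(guards, collapse = ", "),
         call. = FALSE)
  }
  rel <- function(v) {
    (v[1] - tbar[1]) * (v[1] - tbar[2]) * v[2] +
      v[1] * (v[2] - tbar[1]) * (v[2] - tbar[2])
  }
  condition_report(list(x_relation = rel(xbar), y_relation = rel(ybar)))
}

#' Constant-product (inverse-relationship) test for two components
#'
#' Two closed-form components satisfy \eqn{x y = \Omega} identically iff the
#' product of their numerator polynomials equals the product of their
#' denominator polynomials (all monic), in which case
#' \eqn{\Omega = \sigma_x \sigma_y}.
#'
#' @param x_comp,y_comp [lv_component]s (sharing the transformed variable).
#' @return a list with `constant` (logical) and `omega` ([bigq] product
#'   constant when `constant` is `TRUE`, else `NA`).
#' @export
inverse_relation_check <- function(x_comp, y_comp) {
  lhs <- qp_mul(x_comp$num, y_comp$num)
  rhs <- qp_mul(x_comp$den, y_comp$den)
  if (qp_equal(lhs, rhs)) {
    list(constant = TRUE, omega = x_comp$sigma * y_comp$sigma)
  } else {
    list(constant = FALSE, omega = new_bigq(NA_character_))
  }
}
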