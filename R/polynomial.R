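#' Exact univariate polynomials over the rationals
#'
#' A `qpoly` stores ascending coefficients as a [bigq] vector. These
#' polynomials carry all of the symbolic work of the package: the numerator
#' and denominator polynomials \eqn{X_l}, \eqn{Y_l}, \eqn{T} of a solitary
#' solution in the transformed variable \eqn{\hat t = e^{\eta(t-t_0)}}, and
#' every residual identity that certifies a (system, solution) pair.
#'
#' @param coef coefficients in ascending order of degree (anything [bigq()]
#'   accepts).
#' @return an object of class `qpoly`.
#' @export
qpoly <- function(coef) {
  co <- bigq(coef)
  if (length(co) == 0L) co <- bigq("0")
  structure(list(coef = co), class = "qpoly")
}

qp_trim <- function(p) {
  co <- p$coef
  nz <- which(!bq_is_zero(co))
  if (length(nz) == 0L) return(qpoly("0"))
  qpoly(co[seq_len(max(nz))])
}

#' @export
print.qpoly <- function(x, ...) {
  cat("<qpoly deg ", qp_degree(x), "> coef: ",
      paste(unclass(x$coef), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @rdname qpoly
#' @param p,q `qpoly` objects.
#' @export
qp_degree <- function(p) {
  nz <- which(!bq_is_zero(p$coef))
  if (length(nz) == 0L) -1L else max(nz) - 1L
}

#' @rdname qpoly
#' @export
qp_is_zero <- function(p) qp_degree(p) < 0L

pad <- function(x, n) c(x, rep(bigq("0"), n - length(x)))

#' @rdname qpoly
#' @export
qp_add <- function(p, q) {
  n <- max(length(p$coef), length(q$coef))
  qp_trim(qpoly(pad(p$coef, n) + pad(q$coef, n)))
}

#' @rdname qpoly
#' @export
qp_sub <- function(p, q) qp_add(p, qp_neg(q))

#' @rdname qpoly
#' @export
qp_neg <- function(p) qpoly(-p$coef)

#' @rdname qpoly
#' @export
qp_mul <- function(p, q) qp_trim(qpoly(new_bigq(.bq_polymul(p$coef, q$coef))))

#' @rdname qpoly
#' @param s a scalar multiplier.
#' @export
qp_scale <- function(p, s) qp_trim(qpoly(p$coef * bigq(s)))

#' @rdname qpoly
#' @export
qp_equal <- function(p, q) qp_is_zero(qp_sub(p, q))

#' Euler-type derivative \eqn{\hat t \, P'(\hat t)}
#'
#' The transformed system is autonomous in \eqn{\hat t P'}, so this is the
#' derivative operator that appears in every balancing identity: it maps
#' coefficient \eqn{c_k \hat t^k} to \eqn{k c_k \hat t^k}.
#'
#' @param p a [qpoly].
#' @return a [qpoly] of the same degree.
#' @export
qp_that_deriv <- function(p) {
  k <- seq_along(p$coef) - 1L
  qp_trim(qpoly(p$coef * bigq(k)))
}

#' Exact and numeric polynomial evaluation
#'
#' @param p a [qpoly].
#' @param x a single exact rational (for `qp_eval`) or a numeric vector (for
#'   `qp_eval_num`).
#' @return `qp_eval`: a length-one [bigq]; `qp_eval_num`: a numeric vector.
#' @export
qp_eval <- function(p, x) new_bigq(.bq_polyeval(p$coef, bigq(x)))

#' @rdname qp_eval
#' @export
qp_eval_num <- function(p, x) {
  co <- as.numeric(p$coef)
  out <- rep(0, length(x))
  for (i in rev(seq_along(co))) out <- out * x + co[i]
  out
}

#' Expand a monic polynomial from its roots, exactly
#'
#' @param roots a [bigq] vector of roots.
#' @return the monic [qpoly] \eqn{\prod_k (x - r_k)}.
#' @export
qp_from_roots <- function(roots) {
  out <- qpoly("1")
  for (r in seq_along(roots)) {
    out <- qp_mul(out, qpoly(c(-roots[r], bigq(1))))
  }
  out
}

#' All rational roots of an exact polynomial
#'
#' Finds every rational root, exactly. Degree-one factors are solved
#' directly; higher degrees are located numerically with [polyroot()], each
#' real candidate is polished by Newton steps, reconstructed as a rational by
#' continued fractions, verified by exact evaluation, and then deflated out
#' by exact synthetic division so that multiple rational roots are found
#' reliably. Irrational and complex roots are never returned.
#'
#' @param p a [qpoly].
#' @param max_den largest denominator attempted in rational reconstruction.
#' @return a [bigq] vector of distinct verified rational roots (with
#'   multiplicity collapsed).
#' @export
qp_rational_roots <- function(p, max_den = 1e12) {
  p <- qp_trim(p)
  roots <- bigq(character(0))
  # exact zero roots first
  while (qp_degree(p) >= 1L && bq_is_zero(p$coef[1L])) {
    if (!any(bq_sign(roots) == 0L)) roots <- c(roots, bigq(0))
    p <- qpoly(p$coef[-1L])
  }
  repeat {
    d <- qp_degree(p)
    if (d < 1L) break
    if (d == 1L) {
      r <- -p$coef[1L] / p$coef[2L]
      roots <- c(roots, r)
      break
    }
    cand <- qp_real_root_candidates(p)
    found <- FALSE
    for (r in cand) {
      if (bq_is_zero(qp_eval(p, r))) {
        roots <- c(roots, r)
        p <- qp_deflate(p, r)
        found <- TRUE
        break
      }
    }
    if (!found) break
  }
  if (length(roots) == 0L) return(roots)
  roots[!duplicated(unclass(roots))]
}

# numeric real-root candidates reconstructed as rationals (unverified)
qp_real_root_candidates <- function(p, max_den = 1e12) {
  co <- as.numeric(p$coef)
  co <- co / max(abs(co))
  rts <- tryCatch(polyroot(co), error = function(e) complex(0))
  if (length(rts) == 0L) return(list())
  scale <- pmax(1, Mod(rts))
  real <- Re(rts[abs(Im(rts)) < 1e-7 * scale])
  if (length(real) == 0L) return(list())
  # Newton polish in double precision
  dp <- qp_that_deriv(p)
  for (it in 1:4) {
    fv <- qp_eval_num(p, real)
    dv <- qp_eval_num(dp, real) / ifelse(real != 0, real, 1)
    step <- ifelse(dv != 0 & real != 0, fv / dv, 0)
    real <- real - step
  }
  out <- list()
  for (x in unique(real)) {
    # all convergents, best (largest denominator) first; exact evaluation
    # in the caller arbitrates, so near-miss convergents are harmless
    for (r in rev(cf_convergents(x, max_den = max_den))) {
      out[[length(out) + 1L]] <- bigq(r)
    }
  }
  out
}

# all continued-fraction convergents "p/q" of a double with q <= max_den
cf_convergents <- function(x, max_den = 1e12) {
  if (!is.finite(x)) return(character(0))
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
  y <- x
  out <- character(0)
  for (i in 1:64) {
    a <- floor(y)
    p2 <- a * p1 + p0
    q2 <- a * q1 + q0
    if (q2 > max_den || abs(p2) > 2^52) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    out <- c(out, sprintf("%.0f/%.0f", p1, q1))
    frac <- y - a
    if (frac < 1e-15) break
    y <- 1 / frac
  }
  out
}

# exact synthetic division of p by (x - r); r must be an exact root
qp_deflate <- function(p, r) {
  co <- p$coef
  n <- length(co)
  out <- rep(bigq("0"), n - 1L)
  acc <- co[n]
  for (i in (n - 1L):1L) {
    out[i] <- acc
    acc <- co[i] + acc * r
  }
  stopifnot(bq_is_zero(acc))
  qp_trim(qpoly(out))
}

#' Continued-fraction rational reconstruction of a double
#'
#' @param x a double.
#' @param max_den largest admissible denominator.
#' @param tol relative tolerance at which a convergent is accepted.
#' @return a `"p/q"` string, or `NA` if no convergent fits.
#' @export
rational_reconstruct <- function(x, max_den = 1e12, tol = 1e-12) {
  conv <- cf_convergents(x, max_den = max_den)
  # simplest first: the first convergent within tolerance has the smallest
  # denominator among all of them
  for (r in conv) {
    v <- as.numeric(bigq(r))
    if (abs(x - v) <= tol * max(1, abs(x))) return(r)
  }
  NA_character_
}

# ---------------------------------------------------------------------------
# rational functions in one indeterminate over the rationals (num/den qpoly);
# no gcd reduction is performed -- degrees stay small in all uses here

#' Rational functions over exact rationals
#'
#' `qrf` objects are ratios of two [qpoly]s in a single indeterminate. They
#' carry the symbolic elimination in the decay rate \eqn{\eta} used by the
#' inverse solver. Standard arithmetic operators are available; no
#' cancellation is performed (degrees stay small in all internal uses).
#'
#' @param num,den numerator and denominator, [qpoly] or coercible.
#' @return an object of class `qrf`.
#' @export
qrf <- function(num, den = qpoly("1")) {
  if (!inherits(num, "qpoly")) num <- qpoly(num)
  if (!inherits(den, "qpoly")) den <- qpoly(den)
  if (qp_is_zero(den)) stop("qrf with identically zero denominator")
  structure(list(num = qp_trim(num), den = qp_trim(den)), class = "qrf")
}

#' @rdname qrf
#' @param x object to convert or test.
#' @export
as_qrf <- function(x) {
  if (inherits(x, "qrf")) return(x)
  if (inherits(x, "qpoly")) return(qrf(x))
  qrf(qpoly(bigq(x)))
}

#' @rdname qrf
#' @export
qrf_var <- function() qrf(qpoly(c("0", "1")))

#' @export
print.qrf <- function(x, ...) {
  cat("<qrf> (", paste(unclass(x$num$coef), collapse = " "), ") / (",
      paste(unclass(x$den$coef), collapse = " "), ")\n", sep = "")
  invisible(x)
}

#' @export
Ops.qrf <- function(e1, e2) {
  if (nargs() == 1L) {
    if (.Generic == "-") { e1$num <- qp_neg(e1$num); return(e1) }
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for qrf")
  }
  if (.Generic == "^") {
    k <- e2
    stopifnot(is.numeric(k), length(k) == 1L, k == round(k), k >= 0)
    out <- as_qrf(1)
    for (i in seq_len(k)) out <- out * e1
    return(out)
  }
  a <- as_qrf(e1); b <- as_qrf(e2)
  switch(.Generic,
    "+" = qrf(qp_add(qp_mul(a$num, b$den), qp_mul(b$num, a$den)),
              qp_mul(a$den, b$den)),
    "-" = qrf(qp_sub(qp_mul(a$num, b$den), qp_mul(b$num, a$den)),
              qp_mul(a$den, b$den)),
    "*" = qrf(qp_mul(a$num, b$num), qp_mul(a$den, b$den)),
    "/" = {
      if (qp_is_zero(b$num)) stop("division by zero qrf")
      qrf(qp_mul(a$num, b$den), qp_mul(a$den, b$num))
    },
    stop(.Generic, " not defined for qrf")
  )
}

#' Evaluate a rational function exactly
#'
#' @param f a [qrf].
#' @param x a single exact rational.
#' @return a length-one [bigq]; error if `x` is a pole.
#' @export
qrf_eval <- function(f, x) {
  dv <- qp_eval(f$den, x)
  if (bq_is_zero(dv)) stop("qrf evaluated at a pole")
  qp_eval(f$num, x) / dv
}
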