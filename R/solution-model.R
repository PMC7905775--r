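#' Solitary-solution components as ratios of monic polynomials
#'
#' A component represents one closed-form state variable
#' \deqn{x(t) = \sigma \frac{X(\hat t)}{T(\hat t)}, \qquad
#'       \hat t = e^{\eta (t - t_0)},}
#' where \eqn{X} and \eqn{T} are monic polynomials of degree \eqn{n}. The
#' component is stored coefficient-first: the numerator coefficient of
#' \eqn{\hat t^k} is `ratios[k+1] * aes[k+1]` and the shared-denominator
#' coefficient is `aes[k+1]` (\eqn{k = 0, \dots, n-1}), both polynomials
#' having leading coefficient 1. Roots are derived views, never stored: all
#' existence conditions act on coefficients, and roots may be complex while
#' the coefficients stay real.
#'
#' @param sigma amplitude \eqn{\sigma}, an exact rational.
#' @param ratios length-`n` exact vector of numerator-to-denominator
#'   coefficient ratios (the \eqn{p_k} or \eqn{h_k}).
#' @param aes length-`n` exact vector of shared denominator coefficients
#'   (\eqn{\ae_k}).
#' @return an object of class `lv_component` with fields `sigma`, `ratios`,
#'   `aes`, `order`, and derived [qpoly]s `num` (\eqn{\sigma}-free numerator
#'   \eqn{X}) and `den` (\eqn{T}).
#' @examples
#' cmp <- lv_component("4", c("30", "-25", "5"), c("1", "5", "15"))
#' as.character(cmp$num$coef)  # "30" "-125" "75" "1"
#' @export
lv_component <- function(sigma, ratios, aes) {
  sigma <- bigq(sigma)
  ratios <- bigq(ratios)
  aes <- bigq(aes)
  n <- length(ratios)
  if (n < 1L) stop("component order must be at least 1", call. = FALSE)
  if (length(aes) != n) {
    stop("ratios and aes must have equal length (the order n)", call. = FALSE)
  }
  if (length(sigma) != 1L) stop("sigma must be a single rational", call. = FALSE)
  if (all(bq_is_zero(aes))) {
    stop("all denominator coefficients zero: component degenerates to the ",
         "constant sigma", call. = FALSE)
  }
  structure(
    list(sigma = sigma, ratios = ratios, aes = aes, order = n,
         num = qpoly(c(ratios * aes, bigq(1))),
         den = qpoly(c(aes, bigq(1)))),
    class = "lv_component"
  )
}

#' @export
print.lv_component <- function(x, ...) {
  cat("<lv_component> order ", x$order, ", sigma = ", unclass(x$sigma), "\n",
      "  numerator coef:   ", paste(unclass(x$num$coef), collapse = " "), "\n",
      "  denominator coef: ", paste(unclass(x$den$coef), collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' Full four-component solitary solution set
#'
#' Bundles the four closed-form components \eqn{x_1, y_1, x_2, y_2} of the
#' coupled system, which share one denominator \eqn{T} and one order
#' \eqn{n}, together with the decay rate \eqn{\eta} and time shift
#' \eqn{t_0}.
#'
#' @param n order (positive integer).
#' @param eta exact nonzero decay rate \eqn{\eta}.
#' @param t0 exact time shift \eqn{t_0}.
#' @param sigmas length-4 exact vector \eqn{(\sigma_{11}, \sigma_{21},
#'   \sigma_{12}, \sigma_{22})}, i.e. amplitudes of x1, y1, x2, y2.
#' @param aes length-`n` exact vector of shared denominator coefficients.
#' @param ratios list of four length-`n` exact vectors, named `x1`, `y1`,
#'   `x2`, `y2`: the \eqn{p_{k1}, h_{k1}, p_{k2}, h_{k2}} tables.
#' @return an object of class `lv_solution` with a `components` list of four
#'   [lv_component]s plus `n`, `eta`, `t0`.
#' @export
lv_solution <- function(n, eta, t0, sigmas, aes, ratios) {
  eta <- bigq(eta); t0 <- bigq(t0)
  sigmas <- bigq(sigmas); aes <- bigq(aes)
  if (bq_is_zero(eta)) stop("eta must be nonzero", call. = FALSE)
  if (length(sigmas) != 4L) stop("sigmas must have length 4", call. = FALSE)
  nms <- c("x1", "y1", "x2", "y2")
  if (!is.list(ratios) || !all(nms %in% names(ratios))) {
    stop("ratios must be a list with elements x1, y1, x2, y2", call. = FALSE)
  }
  comps <- lapply(seq_along(nms), function(i) {
    r <- bigq(ratios[[nms[i]]])
    if (length(r) != n) {
      stop("ratio table ", nms[i], " must have length n = ", n, call. = FALSE)
    }
    lv_component(sigmas[i], r, aes)
  })
  names(comps) <- nms
  structure(list(n = as.integer(n), eta = eta, t0 = t0, aes = aes,
                 sigmas = sigmas, components = comps),
            class = "lv_solution")
}

#' @export
print.lv_solution <- function(x, ...) {
  cat("<lv_solution> order ", x$n, ", eta = ", unclass(x$eta),
      ", t0 = ", unclass(x$t0), "\n", sep = "")
  for (nm in names(x$components)) {
    cmp <- x$components[[nm]]
    cat("  ", nm, ": sigma = ", unclass(cmp$sigma), ", numerator (",
        paste(unclass(cmp$num$coef), collapse = " "), ")\n", sep = "")
  }
  cat("  shared denominator (", paste(unclass(x$components$x1$den$coef),
      collapse = " "), ")\n", sep = "")
  invisible(x)
}

#' The exponential time transform
#'
#' Maps real time to the transformed variable \eqn{\hat t =
#' e^{\eta (t - t_0)}}, in which all solution components are rational
#' functions. Strictly positive, and monotone increasing in `t` for
#' \eqn{\eta > 0}.
#'
#' @param t numeric vector of times.
#' @param eta exact (or numeric) decay rate.
#' @param t0 exact (or numeric) time shift.
#' @return numeric vector \eqn{\exp(\eta (t - t_0))}.
#' @examples
#' transform_time(5, 1, 5)       # 1
#' transform_time(log(2), 4, 0)  # 16
#' @export
transform_time <- function(t, eta, t0) {
  exp(to_num(eta) * (t - to_num(t0)))
}

to_num <- function(x) {
  if (is_bigq(x)) return(as.numeric(x))
  if (is.character(x)) return(as.numeric(bigq(x)))  # accept "p/q" strings
  as.numeric(x)
}

#' Evaluate a solitary solution on a time grid
#'
#' Evaluates all four components in floating point. Each returned value is
#' \eqn{\sigma_c N_c(\hat t) / T(\hat t)}. A pole of the shared denominator
#' inside the grid is an error naming the offending time.
#'
#' @param sol an [lv_solution].
#' @param t numeric vector of times.
#' @return a data frame with columns `t`, `x1`, `y1`, `x2`, `y2`.
#' @export
evaluate_solution <- function(sol, t) {
  that <- transform_time(t, sol$eta, sol$t0)
  den <- qp_eval_num(sol$components$x1$den, that)
  bad <- which(abs(den) < 1e-12 * pmax(1, that)^sol$n)
  if (length(bad) > 0L) {
    stop("denominator pole at t = ", signif(t[bad[1L]], 10), call. = FALSE)
  }
  out <- data.frame(t = t)
  for (nm in names(sol$components)) {
    cmp <- sol$components[[nm]]
    out[[nm]] <- as.numeric(cmp$sigma) * qp_eval_num(cmp$num, that) / den
  }
  out
}

#' Limits of a component as t tends to plus/minus infinity
#'
#' For \eqn{\eta > 0}: as \eqn{t \to +\infty}, \eqn{\hat t \to \infty} and
#' the ratio of monic leading terms gives \eqn{\sigma}; as
#' \eqn{t \to -\infty}, \eqn{\hat t \to 0} and the constant-term ratio gives
#' \eqn{\sigma\, ratio_0} (when \eqn{\ae_0 \neq 0}). For \eqn{\eta < 0} the
#' two limits swap.
#'
#' @param component an [lv_component].
#' @param eta the exact decay rate the component is used with.
#' @return a named [bigq] vector with elements `t_minus_inf`, `t_plus_inf`;
#'   `NA` where the constant-term ratio is indeterminate (\eqn{\ae_0 = 0}).
#' @export
component_limits <- function(component, eta) {
  at_inf <- component$sigma
  at_zero <- if (bq_is_zero(component$aes[1L])) {
    new_bigq(NA_character_)
  } else {
    component$sigma * component$ratios[1L]
  }
  pos <- bq_sign(bigq(eta)) > 0L
  out <- if (pos) c(at_zero, at_inf) else c(at_inf, at_zero)
  names(out) <- c("t_minus_inf", "t_plus_inf")
  out
}

#' Numerator and denominator roots of a component
#'
#' Derives the root multisets of the monic numerator and denominator
#' polynomials from the stored coefficients. Rational roots are reported
#' exactly (as `"p/q"` strings); the full complex multisets come from
#' numeric root finding.
#'
#' @param component an [lv_component].
#' @return a list with `num_roots`, `den_roots` (complex vectors) and
#'   `num_roots_exact`, `den_roots_exact` ([bigq] vectors of the verified
#'   rational roots).
#' @export
roots_from_coeffs <- function(component) {
  num_c <- as.numeric(component$num$coef)
  den_c <- as.numeric(component$den$coef)
  list(
    num_roots = polyroot(num_c),
    den_roots = polyroot(den_c),
    num_roots_exact = qp_rational_roots(component$num),
    den_roots_exact = qp_rational_roots(component$den)
  )
}

#' Real positive denominator roots mapped back to pole times
#'
#' Only positive real roots of \eqn{T(\hat t)} correspond to real times,
#' since \eqn{\hat t = e^{\eta (t - t_0)} > 0}.
#'
#' @param sol an [lv_solution].
#' @return numeric vector of pole times (possibly empty).
#' @export
pole_times <- function(sol) {
  rts <- polyroot(as.numeric(sol$components$x1$den$coef))
  re <- Re(rts[abs(Im(rts)) < 1e-8 * pmax(1, Mod(rts))])
  re <- re[re > 0]
  if (length(re) == 0L) return(numeric(0))
  sort(log(re) / as.numeric(sol$eta) + as.numeric(sol$t0))
}
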