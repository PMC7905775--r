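#' Arbitrary-precision rational scalars
#'
#' `bigq` vectors hold exact rational numbers as canonical `"p/q"` strings
#' backed by an arbitrary-precision integer kernel. All arithmetic on them is
#' exact: there is no rounding anywhere in the algebra of this package, which
#' is what makes bit-exact reproduction of solitary-solution parameters
#' possible. Floating point enters only when solutions are *evaluated* on a
#' time grid or integrated numerically.
#'
#' Accepted inputs are integers, integer-valued doubles, strings such as
#' `"-34171/31979"` or `"7"`, and existing `bigq` vectors. Non-integer
#' doubles are rejected on purpose: a literal like `0.5` has no exact decimal
#' provenance, so it must be written `"1/2"`.
#'
#' @param x vector to convert: integer, integer-valued double, character in
#'   `"p/q"` form, or `bigq`.
#' @return a `bigq` vector.
#' @examples
#' bigq("1/3") + bigq("1/6")   # exactly 1/2
#' bigq(2)^10                  # 1024, exact
#' @export
bigq <- function(x) {
  if (is_bigq(x)) return(x)
  if (is.character(x)) return(new_bigq(.bq_norm(x)))
  if (is.numeric(x)) {
    bad <- is.finite(x) & x != round(x)
    if (any(bad) || any(!is.finite(x))) {
      stop("non-integer numeric ", paste(x[bad | !is.finite(x)], collapse = ", "),
           " cannot be converted exactly; use a \"p/q\" string such as \"1/2\"",
           call. = FALSE)
    }
    if (any(abs(x) >= 2^53)) {
      stop("numeric too large for exact conversion; pass it as a string", call. = FALSE)
    }
    return(new_bigq(.bq_norm(sprintf("%.0f", x))))
  }
  stop("cannot convert object of class ", paste(class(x), collapse = "/"),
       " to bigq", call. = FALSE)
}

new_bigq <- function(x) structure(as.character(x), class = "bigq")

#' @rdname bigq
#' @export
as.bigq <- bigq

#' @rdname bigq
#' @export
is_bigq <- function(x) inherits(x, "bigq")

#' @export
Ops.bigq <- function(e1, e2) {
  if (nargs() == 1L) {
    if (.Generic == "-") return(new_bigq(.bq_neg(bigq(e1))))
    if (.Generic == "+") return(bigq(e1))
    stop("unary ", .Generic, " not defined for bigq")
  }
  if (.Generic == "^") {
    base <- bigq(e1)
    k <- e2
    if (!is.numeric(k) || length(k) != 1L || k != round(k)) {
      stop("bigq exponent must be a single integer")
    }
    out <- new_bigq(rep("1", length(base)))
    b <- if (k < 0) new_bigq(.bq_div("1", base)) else base
    for (i in seq_len(abs(k))) out <- new_bigq(.bq_mul(out, b))
    return(out)
  }
  a <- bigq(e1); b <- bigq(e2)
  switch(.Generic,
    "+" = new_bigq(.bq_add(a, b)),
    "-" = new_bigq(.bq_sub(a, b)),
    "*" = new_bigq(.bq_mul(a, b)),
    "/" = new_bigq(.bq_div(a, b)),
    "==" = .bq_cmp(a, b) == 0L,
    "!=" = .bq_cmp(a, b) != 0L,
    "<"  = .bq_cmp(a, b) < 0L,
    "<=" = .bq_cmp(a, b) <= 0L,
    ">"  = .bq_cmp(a, b) > 0L,
    ">=" = .bq_cmp(a, b) >= 0L,
    stop(.Generic, " not defined for bigq")
  )
}

#' @export
Math.bigq <- function(x, ...) {
  if (.Generic == "abs") {
    neg <- bq_sign(x) < 0
    out <- unclass(x)
    out[neg] <- .bq_neg(out[neg])
    return(new_bigq(out))
  }
  stop(.Generic, " is not an exact operation on bigq; convert with as.numeric() first")
}

#' @export
Summary.bigq <- function(..., na.rm = FALSE) {
  x <- new_bigq(unlist(lapply(list(...), function(e) unclass(bigq(e)))))
  switch(.Generic,
    sum  = new_bigq(.bq_sum(x)),
    prod = new_bigq(.bq_prod(x)),
    stop(.Generic, " not supported for bigq")
  )
}

#' @export
format.bigq <- function(x, ...) unclass(x)

#' @export
print.bigq <- function(x, ...) {
  cat("<bigq> ", paste(unclass(x), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.bigq <- function(x, ...) unclass(x)

#' @export
as.double.bigq <- function(x, ...) .bq_as_double(x)

#' @export
`[.bigq` <- function(x, i) new_bigq(unclass(x)[i])

#' @export
`[<-.bigq` <- function(x, i, value) {
  out <- unclass(x)
  out[i] <- unclass(bigq(value))
  new_bigq(out)
}

#' @export
c.bigq <- function(...) {
  new_bigq(unlist(lapply(list(...), function(e) unclass(bigq(e)))))
}

#' @export
rep.bigq <- function(x, ...) new_bigq(rep(unclass(x), ...))

#' Sign and zero tests for exact rationals
#'
#' @param x a `bigq` vector.
#' @return `bq_sign` returns -1/0/1 per element; `bq_is_zero` a logical vector.
#' @export
bq_sign <- function(x) .bq_cmp(bigq(x), "0")

#' @rdname bq_sign
#' @export
bq_is_zero <- function(x) bq_sign(x) == 0L

#' Exact square root of a rational, when one exists
#'
#' Returns the nonnegative rational square root where the argument is a
#' perfect square of a rational, and `NA` otherwise (including all negative
#' arguments). Used for the decay rate \eqn{\eta} of kink solutions, which
#' satisfies \eqn{\eta^2 = c_1^2 - 4 c_0 c_2}.
#'
#' @param x a `bigq` vector.
#' @return a `bigq` vector with `NA` entries where no exact root exists.
#' @export
bq_sqrt <- function(x) new_bigq(.bq_sqrt(bigq(x)))
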