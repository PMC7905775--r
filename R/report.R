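#' Condition reports
#'
#' A uniform container for the outcome of exact condition checks: a named
#' list of residuals (exact rationals where the check is exact, doubles
#' where it is numeric) and the names of any violated structural guards.
#' The report passes iff every exact residual is zero, every numeric
#' residual is below its tolerance, and no guard is violated.
#'
#' @param residuals named list of residual values ([bigq] scalars or
#'   numerics).
#' @param guards_violated character vector naming violated guards.
#' @param tol tolerance applied to numeric residuals.
#' @return an object of class `condition_report` with fields `residuals`,
#'   `guards_violated`, `pass`.
#' @export
condition_report <- function(residuals = list(), guards_violated = character(0),
                             tol = 1e-9) {
  ok <- vapply(residuals, function(r) {
    if (is_bigq(r)) all(bq_is_zero(r)) else all(abs(r) <= tol)
  }, logical(1))
  structure(
    list(residuals = residuals, guards_violated = guards_violated,
         pass = all(ok) && length(guards_violated) == 0L),
    class = "condition_report"
  )
}

#' @export
print.condition_report <- function(x, ...) {
  cat("<condition_report> ", if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  for (nm in names(x$residuals)) {
    r <- x$residuals[[nm]]
    cat("  ", nm, " = ", if (is_bigq(r)) paste(unclass(r), collapse = " ")
        else paste(signif(r, 6), collapse = " "), "\n", sep = "")
  }
  if (length(x$guards_violated) > 0L) {
    cat("  violated guards: ", paste(x$guards_violated, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
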