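#' Bundled third-order reference instance
#'
#' A fully worked third-order instance used throughout the tests: free
#' choices \eqn{A_{11} = 4/5}, \eqn{A_{12} = 2/5},
#' \eqn{h_{12} = 139919/7619}, \eqn{h_{22} = 39493/15238}, denominator
#' coefficients \eqn{(8, 14, 7)}, rate \eqn{\eta = 4}, shift
#' \eqn{t_0 = -5}, and amplitudes
#' \eqn{(\sigma_{11}, \sigma_{21}, \sigma_{12}, \sigma_{22}) =
#' (3/5,\ 7834855/274284,\ 7/15,\ 685710/223853)}.
#'
#' Besides the certified triple, the fixture carries `quarter_system`: the
#' same assembly evaluated at rate 1 instead of 4 (every model coefficient
#' is linear in \eqn{\eta}, so this is exactly the assembled system with
#' all 18 coefficients divided by 4). The \eqn{\eta = 4} solution does
#' **not** satisfy `quarter_system`; it is kept as a regression artifact
#' for the rate-scaling property.
#'
#' @return a list with `aux`, `solution`, `system` (the certified triple)
#'   and `quarter_system` (an [lv_system]).
#' @export
fixture_third_order <- function() {
  fixed <- list(A11 = "4/5", A12 = "2/5",
                h12 = "139919/7619", h22 = "39493/15238")
  sigmas <- c("3/5", "7834855/274284", "7/15", "685710/223853")
  tr <- assemble_full(3, fixed, aes = c(8, 14, 7), sigmas = sigmas,
                      eta = 4, t0 = -5)
  quarter <- assemble_system(tr$aux, sigmas, eta = 1)
  list(aux = tr$aux, solution = tr$solution, system = tr$system,
       quarter_system = quarter)
}

#' Bundled diffusively coupled Lotka-Volterra instance
#'
#' The second worked instance: a concrete coupled Lotka-Volterra system
#' together with the third-order solitary solution that solves it
#' identically. Free choices \eqn{A_{11} = 4/5}, \eqn{A_{12} = 2/5},
#' \eqn{h_{12} = -25}, \eqn{h_{22} = 5}; denominator coefficients
#' \eqn{(1, 5, 15)}; \eqn{\eta = 1}, \eqn{t_0 = -5}; amplitudes
#' \eqn{(\sigma_{11}, \sigma_{21}, \sigma_{12}, \sigma_{22}) =
#' (1, 3, 2, 4)}.
#'
#' @return a list with `aux`, `solution`, `system`.
#' @export
fixture_coupled_lv <- function() {
  fixed <- list(A11 = "4/5", A12 = "2/5", h12 = "-25", h22 = "5")
  tr <- assemble_full(3, fixed, aes = c(1, 5, 15),
                      sigmas = c(1, 3, 2, 4), eta = 1, t0 = -5)
  list(aux = tr$aux, solution = tr$solution, system = tr$system)
}

#' Bundled kink (first-order Riccati) instance
#'
#' The scalar Riccati equation \eqn{x' = -1 + 5x - 4x^2}, whose
#' equilibria are \eqn{1/4} and \eqn{1}, and the kink solution through
#' \eqn{x(0) = 1/2}.
#'
#' @return a list with `equation` ([lv_riccati]) and `kink` (the result of
#'   [kink_from_coeffs()]).
#' @export
fixture_kink <- function() {
  eq <- lv_riccati(-1, 5, -4)
  list(equation = eq, kink = kink_from_coeffs(eq, x_init = "1/2"))
}

#' Bundled multiplicatively coupled Riccati pair instance
#'
#' A coupled pair
#' \eqn{x' = a_0 + a_1 x + a_2 x^2 + a_3 x y},
#' \eqn{y' = b_0 + b_1 y + b_2 y^2 + b_3 x y}
#' satisfying all existence conditions exactly, with rational rate
#' \eqn{\eta = 1}.
#'
#' @return an [lv_pair].
#' @export
fixture_pair <- function() {
  lv_pair(a = c("136/11", "-828/319", "29/187", "-550/1479"),
          b = c("-51/29", "345/319", "-550/1479", "29/187"))
}
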