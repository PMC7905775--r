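# lvsoliton

Exact construction, inversion, and verification of higher-order solitary
solutions for diffusively coupled Lotka–Volterra (Riccati-type) systems.

## The model

The package studies the four-equation model

```
x_l' = a_0l + a_1l x_l + a_2l x_l^2 + λ_l x_l y_l
y_l' = b_0l + b_1l y_l + b_2l y_l^2 + μ_l x_l y_l + γ_l (y_r − y_l),   l = 1, 2,  r ≠ l
```

two Riccati pairs coupled multiplicatively within a pair (`λ`, `μ`) and
diffusively between pairs (`γ`). For suitable coefficients it admits
closed-form *solitary solutions of order n*,

```
x(t) = σ · X(t̂) / T(t̂),     t̂ = exp(η (t − t0)),
```

where `X` and `T` are monic polynomials of degree `n` sharing one
denominator `T` across all four components. The order-1 case is the
familiar Riccati kink (a monotone transition between two equilibria);
higher orders produce richer transition shapes, still monotone between
poles.

Everything is stored *coefficient-first*: a component is defined by the
ratios `p_k = X_k / T_k` (or `h_k` for the y components) and the shared
denominator coefficients `æ_k`, all exact rationals. Roots are derived
views. The algebraic skeleton is:

- `A_2l = −(1 + A_1l)/n` and `p_kl = 1 / (1 + (n − k) A_2l)` tie the
  x-ratios to one free choice `A_1l` per subsystem;
- the balancing equations `k + L_1l + L_2l p_kl + L_3l h_kl = 0` tie the
  y-ratios to the `L` triple (for `n ≥ 2` the `L` and `N` triples
  coincide and are uniquely determined by `p_0, p_1, h_0, h_1`);
- the coupling equations `h_kr + K_1l h_kl + K_2l + K_3l k h_kl = 0`
  constrain the two subsystems to each other;
- a coefficient map sends the auxiliary parameters
  `(A, L, N, K, η, σ)` to the 18 model coefficients.

An *order dichotomy* governs solvability: orders `n ≤ 3` need no extra
conditions, while `n > 3` requires exactly `n − 3` of the shared
denominator coefficients `æ_k` to vanish; with fewer zeroed coefficients
the condition system is overdetermined and generically has no solution.

All algebra is exact. Rational arithmetic is provided by a small GMP-backed
`bigq` class (`src/bigq.cpp`), polynomials and univariate rational
functions on top of it, so every existence condition, residual, and
round-trip is checked bit-exactly, never to a tolerance. Floating point
appears only in evaluation, plotting-oriented trajectories, and the
redundant numerical-integration cross-check.

## Worked example

Construct a third-order solitary solution and the coupled Lotka–Volterra
system it solves, from four free rational choices:

```r
library(lvsoliton)
tr <- assemble_full(
  n = 3,
  fixed = list(A11 = "4/5", A12 = "2/5", h12 = "-25", h22 = "5"),
  aes = c(1, 5, 15), sigmas = c(1, 3, 2, 4), eta = 1, t0 = -5)
tr$system
#> x1' = 5/3 + -16/9 x + -68/5 x^2 + 617/135 x y
#> y1' = 153745/31467 + -656207/377604 y + 617/135 y^2 + -68/5 x y + -243/41956 (y_other - y)
#> x2' = 30/7 + -172/63 x + 68/315 x^2 + 7/180 x y
#> y2' = -740/153 + 6317/3213 y + 7/180 y^2 + 68/315 x y + 2468/459 (y_other - y)
tr$solution
#> <lv_solution> order 3, eta = 1, t0 = -5
#>   x1: sigma = 1, numerator (-5/4 -25 75/2 1)
#>   y1: sigma = 3, numerator (-625/617 -14825/617 23700/617 1)
#>   x2: sigma = 2, numerator (-5/2 75 225/8 1)
#>   y2: sigma = 4, numerator (30 -125 75 1)
#>   shared denominator (1 5 15 1)
```

The solution solves the system *identically* — the residual of each model
equation, reduced to a polynomial in `t̂`, is the zero polynomial:

```r
ode_residual(tr$system, tr$solution)$pass
#> [1] TRUE
```

The inverse direction recovers the generating parameters from the 18
model coefficients alone (the amplitudes are supplied: they are
constrained by the system, not free gauge — see `?recover_parameters`):

```r
br <- recover_parameters(tr$system, n = 3, sigmas = c(1, 3, 2, 4))
length(br)                  # 1 branch
as.character(br[[1]]$eta)   # "1"
```

A redundant numerical cross-check integrates the ODEs and compares with
the closed form:

```r
integrate_and_compare(tr$system, tr$solution, c(0, 10))
#> [1] 5.819096e-10
```

The order-1 base case, a Riccati kink:

```r
kk <- kink_from_coeffs(lv_riccati("-1", "5", "-4"), x_init = "1/2")
kk$solution
#> <lv_kink> sigma = 1, x0 = 1/4, t0 = 1, s = -2, eta = 3
kink_residual(kk$solution, lv_riccati("-1", "5", "-4"))$pass
#> [1] TRUE
```

## Main entry points

| Area | Functions |
| --- | --- |
| Exact arithmetic | `bigq`, `qpoly`, `qrf`, `qp_rational_roots`, `rational_reconstruct` |
| Solution model | `lv_component`, `lv_solution`, `evaluate_solution`, `component_limits`, `pole_times`, `roots_from_coeffs` |
| Order-1 base case | `lv_riccati`, `riccati_eta`, `kink_from_coeffs`, `kink_residual`, `lv_pair`, `pair_existence_check`, `pair_eta`, `inverse_relation_check` |
| Forward constructor | `solve_A`, `solve_LN_unique`, `h_from_L`, `solve_K`, `solve_free_constraints`, `assemble_system`, `assemble_full` |
| Inverse solver | `check_coeff_constraints`, `recover_parameters`, `recover_solution` |
| Verification | `residual_identities`, `ode_residual`, `integrate_and_compare`, `generate_fixture`, bundled `fixture_*()` |
| I/O and CLI | `object_to_list`/`object_from_list`, `emit_report`, `parse_config`, `inst/cli/lvsoliton` |

The command-line tool (run as
`Rscript $(Rscript -e 'cat(find.package("lvsoliton"))')/cli/lvsoliton <command>`)
exposes `construct`, `invert`, `verify`, `kink`, `pair-check`, `fixture`,
and `simulate` over JSON configurations in which every rational is a
`"p/q"` string; serialization round-trips are bit-exact.

## Installation and reproduction

Requires R with `Rcpp`, `jsonlite`, `deSolve`, `optparse`, `testthat`,
and GMP headers (for the exact-arithmetic backend).

```sh
R CMD INSTALL --no-docs --no-html --no-help .
```

Run the full test suite against the installed package (unit, property,
and acceptance tests; the acceptance file takes a few minutes as it
exercises hundreds of random seeded instances):

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "lvsoliton", load_package = "installed")'
```

Recompute the reference-value report:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

which writes one entry per target quantity, each computed at runtime in
exact arithmetic from the worked third-order instances.
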