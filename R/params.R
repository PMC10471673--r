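## Model parameters: the coefficient set of the age-structured
## reaction-diffusion SI model
##
##   dS/dt = d1 Lap S + kappa1 (1 - S/kappa2) S - S int b I da + int r I da
##   (d/dt + d/da) I = d(a) Lap I - (m + r) I
##   I(t, 0, x) = S(t, x) int b(a, x) I(t, a, x) da
##
## on a bounded domain with Dirichlet (delta = 0) or Neumann (delta = 1)
## boundary conditions. kappa1 is the intrinsic logistic growth rate of the
## susceptibles (1/time), kappa2 the carrying capacity (density), d(a) the
## infected diffusion coefficient, m the combined natural/disease mortality,
## r the recovery rate and b the transmission rate. Infection age lives on
## [0, a_m] with a_m finite.

#' General model parameters
#'
#' Container for the coefficients of the infection-age-structured
#' reaction-diffusion epidemic model. Rates may depend on infection age and
#' space; they are supplied as constants, as functions of age `f(a)`, or as
#' functions `f(a, X)` of age and a coordinate matrix `X` (one row per grid
#' node) returning a vector over nodes.
#'
#' @param kappa1 intrinsic logistic growth rate of susceptibles (> 0).
#' @param kappa2 carrying capacity (> 0).
#' @param d1 susceptible diffusion rate (> 0, default 1).
#' @param d infected diffusion coefficient, constant or function of age;
#'   must be bounded below by a positive constant.
#' @param m combined mortality rate (>= 0), constant or function of age
#'   (and space).
#' @param r recovery rate (>= 0), constant or function of age (and space).
#' @param b transmission rate (>= 0, not identically zero), constant or
#'   function of age (and space).
#' @param a_m maximal infection age (finite, > 0).
#' @param L domain extent: a length for an interval \[0, L\], or a vector of
#'   two lengths for a rectangle.
#' @param delta boundary flag: 0 = Dirichlet, 1 = Neumann.
#' @return An object of class `model_params`.
#' @seealso [hom_params()] for the spatially homogeneous Neumann case.
#' @export
model_params <- function(kappa1, kappa2, d1 = 1, d = 1, m = 0, r = 0, b,
                         a_m, L = 1, delta = 1) {
  stop_if_not_scalar_pos(kappa1, "kappa1")
  stop_if_not_scalar_pos(kappa2, "kappa2")
  stop_if_not_scalar_pos(d1, "d1")
  stop_if_not_scalar_pos(a_m, "a_m")
  if (!is.finite(a_m)) stop("a_m must be finite")
  if (!delta %in% c(0, 1)) stop("delta must be 0 (Dirichlet) or 1 (Neumann)")
  if (!is.numeric(L) || !all(L > 0) || !length(L) %in% 1:2) {
    stop("L must be one or two positive lengths")
  }
  p <- structure(
    list(kappa1 = kappa1, kappa2 = kappa2, d1 = d1,
         d = as_age_fun(d, a_m, "d"),
         m = as_agespace_fun(m, a_m, "m"),
         r = as_agespace_fun(r, a_m, "r"),
         b = as_agespace_fun(b, a_m, "b"),
         a_m = a_m, L = L, delta = delta),
    class = "model_params")
  validate_params(p)
  p
}

#' Spatially homogeneous parameters (Neumann boundary conditions)
#'
#' The specialization of [model_params()] in which the rates depend on
#' infection age only and the boundary condition is Neumann. In this setting
#' the basic reproduction number and the endemic steady state have closed
#' forms ([r0_homogeneous()], [endemic_state()]).
#'
#' @inheritParams model_params
#' @param b transmission rate, constant or function of age; must be strictly
#'   positive on \[0, a_m\].
#' @return An object of class `hom_params` (inheriting from `model_params`).
#' @export
hom_params <- function(kappa1 = 1, kappa2 = 1, d1 = 1, d = 1, m = 0.5, r = 0,
                       b, a_m = 2, L = 1) {
  stop_if_not_scalar_pos(kappa1, "kappa1")
  stop_if_not_scalar_pos(kappa2, "kappa2")
  stop_if_not_scalar_pos(a_m, "a_m")
  p <- structure(
    list(kappa1 = kappa1, kappa2 = kappa2, d1 = d1,
         d = as_age_fun(d, a_m, "d"),
         m = as_age_fun(m, a_m, "m"),
         r = as_age_fun(r, a_m, "r"),
         b = as_age_fun(b, a_m, "b"),
         a_m = a_m, L = L, delta = 1),
    class = c("hom_params", "model_params"))
  validate_params(p)
  ab <- seq(0, a_m, length.out = 257L)
  if (any(p$b(ab) <= 0)) stop("b must be strictly positive on [0, a_m]")
  p
}

#' @exportS3Method base::print
print.model_params <- function(x, ...) {
  kind <- if (inherits(x, "hom_params")) "spatially homogeneous" else "general"
  bc <- if (x$delta == 1) "Neumann" else "Dirichlet"
  cat(sprintf(
    "<%s model parameters>\n  kappa1 = %g, kappa2 = %g, d1 = %g, a_m = %g\n  domain L = %s, %s boundary conditions\n",
    kind, x$kappa1, x$kappa2, x$d1, x$a_m,
    paste(x$L, collapse = " x "), bc))
  invisible(x)
}

## Evaluate an age coefficient over the age argument for either parameter
## class (homogeneous: f(a); general: f(a, X) at grid coordinates X).
eval_coef <- function(p, which, a, X = NULL) {
  f <- p[[which]]
  if (inherits(p, "hom_params")) {
    v <- f(a)
    if (is.null(X)) return(v)
    return(matrix(rep(v, each = nrow(X)), nrow = nrow(X)))
  }
  if (is.null(X)) stop("general parameters need grid coordinates")
  if (length(a) == 1L) return(f(a, X))
  vapply(a, function(ai) f(ai, X), numeric(nrow(X)))
}

validate_params <- function(p) {
  ab <- seq(0, p$a_m, length.out = 257L)
  dv <- p$d(ab)
  if (any(!is.finite(dv)) || any(dv <= 0)) {
    stop("d(a) must be positive and bounded away from zero on [0, a_m]")
  }
  if (inherits(p, "hom_params")) {
    mv <- p$m(ab); rv <- p$r(ab); bv <- p$b(ab)
  } else {
    X <- cbind(seq(0, p$L[1], length.out = 9L))
    if (length(p$L) == 2L) {
      X <- as.matrix(expand.grid(X[, 1], seq(0, p$L[2], length.out = 9L)))
    }
    mv <- vapply(ab, function(a) min(p$m(a, X)), 0)
    rv <- vapply(ab, function(a) min(p$r(a, X)), 0)
    bv <- vapply(ab, function(a) max(p$b(a, X)), 0)
  }
  if (any(mv < 0) || any(rv < 0)) stop("m and r must be nonnegative")
  if (any(bv < 0)) stop("b must be nonnegative")
  if (all(bv == 0)) stop("b must not be identically zero")
  invisible(p)
}

#' Survival probability to infection age a
#'
#' The probability `Pi(a) = exp(-int_0^a m(s) ds)` that an infected
#' individual is still infected (alive and not removed by mortality) at
#' infection age `a`. Computed by cumulative composite-trapezoid quadrature
#' of the mortality rate followed by exponentiation; the resolution is
#' refined until a half-resolution Richardson check agrees to `rtol`.
#'
#' @param params a [hom_params()] object.
#' @param a infection age(s) in \[0, a_m\].
#' @param n number of quadrature nodes per evaluation (odd numbers keep the
#'   half grid nested).
#' @param rtol relative tolerance of the Richardson consistency check.
#' @return Survival probabilities, same length as `a`; `Pi(0) = 1` and `Pi`
#'   is nonincreasing for nonnegative mortality.
#' @export
survival_Pi <- function(params, a, n = 2001L, rtol = 1e-10) {
  stopifnot(inherits(params, "hom_params"))
  if (any(a < -1e-12) || any(a > params$a_m + 1e-12)) {
    stop("a must lie in [0, a_m]")
  }
  a <- pmin(pmax(a, 0), params$a_m)
  vapply(a, function(ai) {
    exp(-quad_checked(params$m, ai, n = n, rtol = rtol))
  }, numeric(1))
}

#' Basic reproduction number for homogeneous rates
#'
#' In the spatially homogeneous Neumann case the basic reproduction number
#' is the closed form `R0 = kappa2 * int_0^{a_m} b(a) Pi(a) da`, the expected
#' number of secondary infections produced by one infected individual in a
#' susceptible population at carrying capacity. Evaluated by composite
#' trapezoid quadrature on a uniform age grid with a Richardson refinement
#' check.
#'
#' @inheritParams survival_Pi
#' @return The basic reproduction number (strictly positive).
#' @export
r0_homogeneous <- function(params, n = 2001L, rtol = 1e-10) {
  stopifnot(inherits(params, "hom_params"))
  eval_r0 <- function(n) {
    a <- seq(0, params$a_m, length.out = n)
    h <- a[2] - a[1]
    Pi <- exp(-cumtrapz(params$m(a), h))
    params$kappa2 * trapz(params$b(a) * Pi, h)
  }
  v <- eval_r0(n)
  ## Richardson check with nested refinement for rough coefficients
  for (i in 1:4) {
    n <- 2L * n - 1L
    v2 <- eval_r0(n)
    if (abs(v2 - v) <= max(rtol * abs(v2), 1e-14)) return(v)
    v <- v2
  }
  v
}

#' Endemic steady state for homogeneous rates
#'
#' For homogeneous Neumann parameters with `R0 > 1` the model has the
#' explicit spatially constant endemic steady state
#' `S* = kappa2 / R0` and
#' `I*(a) = (1/R0) kappa1 kappa2 (1 - 1/R0) Pi(a)`.
#'
#' When grids are supplied, `R0` and the survival curve are evaluated with
#' the trapezoid rule on the age grid itself, so that the returned state is
#' a fixed point of the discrete dynamics (and of the discrete steady-state
#' system) to round-off.
#'
#' @param params a [hom_params()] object with `r0_homogeneous(params) > 1`.
#' @param grids optional grid pair from [model_grids()].
#' @param n quadrature resolution when no grids are given.
#' @return A `steady_state` object of kind `"endemic"` with fields `S_star`
#'   (vector over space nodes, or length 1 without grids) and `I_star`
#'   (age-by-space matrix, or age vector without grids).
#' @export
endemic_state <- function(params, grids = NULL, n = 2001L) {
  stopifnot(inherits(params, "hom_params"))
  if (is.null(grids)) {
    a <- seq(0, params$a_m, length.out = n)
    nx <- 1L
  } else {
    a <- grids$age$a
    nx <- grids$space$nx
  }
  h <- a[2] - a[1]
  Pi <- exp(-cumtrapz(params$m(a), h))
  R0 <- params$kappa2 * trapz(params$b(a) * Pi, h)
  if (R0 <= 1) {
    stop("no endemic state: R0 = ", format(R0), " <= 1")
  }
  r0 <- 1 / R0
  S <- rep(params$kappa2 * r0, nx)
  i_star <- r0 * params$kappa1 * params$kappa2 * (1 - r0)
  I <- outer(i_star * Pi, rep(1, nx))
  new_steady_state("endemic", S_star = S, I_star = I, R0 = R0,
                   ages = a, grids = grids)
}

#' Logistic production rate
#'
#' The susceptible production term `kappa1 (1 - S/kappa2) S` of the model.
#' Its maximum over `S >= 0` is `kappa1 kappa2 / 4`, the production cap used
#' in the mass-balance estimates.
#'
#' @param params a [model_params()] object.
#' @param S susceptible density (vectorized).
#' @return Production rate, same shape as `S`.
#' @export
logistic_production <- function(params, S) {
  params$kappa1 * (1 - S / params$kappa2) * S
}
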