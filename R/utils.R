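#' @importFrom Matrix Diagonal Cholesky solve lu bandSparse kronecker Matrix
#' @importFrom methods as
#' @importFrom stats optimize runif approxfun
#' @importFrom utils write.csv read.csv tail packageVersion
NULL

## Composite-trapezoid weights on a uniform grid with n nodes and spacing h.
trapz_weights <- function(n, h) {
  stopifnot(n >= 2)
  w <- rep(h, n)
  w[c(1L, n)] <- h / 2
  w
}

## Trapezoid integral of sampled values y on a uniform grid with spacing h.
trapz <- function(y, h) {
  n <- length(y)
  if (n < 2) return(0)
  sum(trapz_weights(n, h) * y)
}

## Cumulative trapezoid: F[k] = int_{x_1}^{x_k} y dx on a uniform grid.
cumtrapz <- function(y, h) {
  n <- length(y)
  if (n < 2) return(rep(0, n))
  c(0, cumsum((y[-n] + y[-1]) * h / 2))
}

## Coerce a scalar / vector / function coefficient of age into a vectorized
## function of age. Vectors are interpreted as samples on `nodes` (linear
## interpolation, constant extrapolation at the ends).
as_age_fun <- function(f, a_m, name = "coefficient", nodes = NULL) {
  if (is.function(f)) {
    return(function(a) {
      v <- f(a)
      if (length(v) == 1L && length(a) > 1L) v <- rep(v, length(a))
      v
    })
  }
  if (is.numeric(f) && length(f) == 1L) {
    val <- f
    return(function(a) rep(val, length(a)))
  }
  if (is.numeric(f)) {
    if (is.null(nodes)) nodes <- seq(0, a_m, length.out = length(f))
    if (length(nodes) != length(f)) {
      stop(name, ": sampled coefficient and age nodes have different lengths")
    }
    fi <- stats::approxfun(nodes, f, rule = 2)
    return(function(a) fi(a))
  }
  stop(name, " must be a number, a numeric vector, or a function of age")
}

## Coerce a coefficient of (age, space) into a function f(a, X) returning a
## vector over the rows of the coordinate matrix X. Accepts scalars,
## functions of age alone, or functions of (a, x).
as_agespace_fun <- function(f, a_m, name = "coefficient") {
  if (is.numeric(f) && length(f) == 1L) {
    val <- f
    return(function(a, X) rep(val, nrow(X)))
  }
  if (is.function(f)) {
    nf <- length(formals(f))
    if (nf == 1L) {
      return(function(a, X) rep(f(a)[1L], nrow(X)))
    }
    return(function(a, X) {
      v <- f(a, X)
      if (length(v) == 1L) v <- rep(v, nrow(X))
      v
    })
  }
  stop(name, " must be a number or a function of age (and space)")
}

## Quadrature with a Richardson consistency check: integrate f on [0, upper]
## by composite trapezoid at n and 2n-1 nodes; refine until the relative
## change is below rtol (smooth integrands converge at second order).
quad_checked <- function(f, upper, n = 2001L, rtol = 1e-10, max_refine = 3L) {
  if (upper == 0) return(0)
  val <- NA_real_
  for (i in 0:max_refine) {
    a1 <- seq(0, upper, length.out = n)
    a2 <- seq(0, upper, length.out = 2L * n - 1L)
    v1 <- trapz(f(a1), a1[2] - a1[1])
    v2 <- trapz(f(a2), a2[2] - a2[1])
    val <- v2
    if (abs(v2 - v1) <= rtol * max(abs(v2), 1e-300)) break
    n <- 2L * n - 1L
  }
  val
}

## Weighted norms over a grid inner product (weights w).
grid_norm2 <- function(v, w) sqrt(sum(w * v^2))
grid_norm1 <- function(v, w) sum(w * abs(v))

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(name, " must be a positive finite number")
  }
  invisible(x)
}
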