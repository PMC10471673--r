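## Shared fixtures and independent oracles. Everything is built in code at
## test time; scenario grids are kept small so the whole suite stays fast.

fix_hom <- function(R0, nx = 21L, K = 40L) {
  make_scenario(R0, "homogeneous_neumann", nx = nx, K = K)
}

## Closed-form evolution operator for homogeneous data (diffusion-decay
## factorizes): U_A(a, sigma) = exp(-int m) exp(int d * Lap), applied via
## the eigen-decomposition of the discrete Laplacian. Independent of the
## sub-stepping implementation.
oracle_evolution <- function(params, grid, a, sigma, v) {
  ep <- laplacian_eigenpairs(grid)
  Tdiff <- stats::integrate(function(x) params$d(x), sigma, a,
                            rel.tol = 1e-12)$value
  mdec <- stats::integrate(function(x) params$m(x) + params$r(x), sigma, a,
                           rel.tol = 1e-12)$value
  coef <- t(ep$vectors) %*% (grid$w * v)
  exp(-mdec) * as.numeric(ep$vectors %*% (exp(-ep$values * Tdiff) * coef))
}

## Independent space-free reduction of the homogeneous Neumann model:
## method-of-lines with first-order upwind age transport and Heun (RK2)
## time stepping on a fine age grid. Different discretization from the
## package's characteristic scheme.
oracle_spacefree <- function(params, S0, I0_of_a, t_end, K = 600L,
                             substeps = 2L) {
  a <- seq(0, params$a_m, length.out = K + 1L)
  da <- a[2] - a[1]
  wa <- trapz_wts(K + 1L, da)
  mv <- params$m(a); rv <- params$r(a); bv <- params$b(a)
  k1 <- params$kappa1; k2 <- params$kappa2
  rhs <- function(S, I) {
    intb <- sum(wa * bv * I)
    dI <- numeric(K + 1L)
    dI[-1L] <- -(I[-1L] - I[-(K + 1L)]) / da - (mv[-1L] + rv[-1L]) * I[-1L]
    ## age-zero node is slaved to the renewal condition; treat via stiff
    ## relaxation replaced by direct algebraic update after each stage
    dS <- k1 * (1 - S / k2) * S - S * intb + sum(wa * rv * I)
    list(dS = dS, dI = dI)
  }
  renew <- function(S, I) {
    rest <- sum(wa[-1L] * bv[-1L] * I[-1L])
    I[1L] <- S * rest / (1 - S * wa[1L] * bv[1L])
    I
  }
  dt <- da / substeps
  n <- ceiling(t_end / dt)
  S <- S0; I <- renew(S0, I0_of_a(a))
  for (i in seq_len(n)) {
    f1 <- rhs(S, I)
    S1 <- S + dt * f1$dS; I1 <- renew(S1, I + dt * f1$dI)
    f2 <- rhs(S1, I1)
    S <- S + dt * (f1$dS + f2$dS) / 2
    I <- renew(S, I + dt * (f1$dI + f2$dI) / 2)
  }
  list(a = a, wa = wa, S = S, I = I)
}

trapz_wts <- function(n, h) {
  w <- rep(h, n); w[c(1L, n)] <- h / 2; w
}

total_infected <- function(state, grids) {
  sum(grids$age$wa * (state$I %*% grids$space$w))
}
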