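test_that("evolution operator basics: identity, decay limit, contraction", {
  sc <- fix_hom(2, nx = 15L, K = 20L)
  p <- sc$params; g <- sc$grids
  v <- 1 + 0.3 * cos(pi * g$space$X[, 1])
  expect_equal(evolution_apply(p, g, 0.5, 0.5, v), v)
  expect_error(evolution_apply(p, g, 0.2, 0.5, v), "sigma <= a")
  ## (near-)zero diffusion: pure exponential decay e^{-m (a - sigma)}
  pz <- hom_params(kappa1 = 1, kappa2 = 1, m = 0.7, b = 1, a_m = 2,
                   d = 1e-12)
  u <- evolution_apply(pz, g, 1.5, 0.5, v)
  expect_equal(u, exp(-0.7) * v, tolerance = 1e-8)
  ## grid 1-norm contraction for m >= 0
  u2 <- evolution_apply(p, g, 2, 0, abs(v))
  expect_lte(sum(g$space$w * abs(u2)), sum(g$space$w * abs(v)))
  expect_true(all(u2 > 0))
})

test_that("evolution operator matches the homogeneous closed form after
           Richardson extrapolation", {
  p <- hom_params(kappa1 = 1, kappa2 = 1, m = 0.5, b = 1, a_m = 2, d = 1)
  g1 <- model_grids(p, nx = 41L, K = 50L)
  g2 <- model_grids(p, nx = 41L, K = 100L)
  v <- 1 + 0.5 * cos(pi * g1$space$X[, 1]) + 0.2 * cos(2 * pi * g1$space$X[, 1])
  u1 <- evolution_apply(p, g1, 2, 0, v)
  u2 <- evolution_apply(p, g2, 2, 0, v)
  ex <- oracle_evolution(p, g1$space, 2, 0, v)
  expect_lt(max(abs(2 * u2 - u1 - ex)), 1e-8)
})

test_that("Q^lambda assembly: positivity, monotone decay, dominated limit", {
  sc <- fix_hom(2, nx = 15L, K = 30L)
  p <- sc$params; g <- sc$grids
  Q0 <- q_lambda(p, g, 0)
  Q1 <- q_lambda(p, g, 1)
  expect_true(all(Q0$matrix >= 0))
  expect_true(all(Q0$matrix - Q1$matrix >= -1e-14))  # entrywise decrease
  ## dominated decay at lambda = 50: the operator 1-norm is capped by the
  ## damped quadrature sum (column sums of U_A(a,0) equal Pi(a) under
  ## Neumann conditions) and is far below the lambda = 0 norm
  Q50 <- q_lambda(p, g, 50)
  a <- g$age$a
  Pi <- exp(-cumsum(c(0, (p$m(a[-1]) + p$m(a[-length(a)])) / 2 * g$age$da)))
  cap <- sum(g$age$wa * p$b(a) * exp(-50 * a) * Pi)
  expect_lt(max(colSums(abs(Q50$matrix))), cap + 1e-10)
  expect_lt(cap, 0.05 * max(colSums(Q0$matrix)))
  ## homogeneous Neumann: S~ Q^0 1 = kappa2 int b Pi da * 1
  one <- rep(1, 15)
  lhs <- p$kappa2 * as.numeric(Q0$matrix %*% one)
  a <- g$age$a
  Pi <- exp(-cumsum(c(0, (p$m(a[-1]) + p$m(a[-31])) / 2 * g$age$da)))
  rhs <- p$kappa2 * sum(g$age$wa * p$b(a) * Pi)
  expect_equal(lhs, rep(rhs, 15), tolerance = 1e-12)
})

test_that("weighted spectral radius: closed form, linearity, positivity", {
  sc <- fix_hom(2, nx = 15L, K = 60L)
  p <- sc$params; g <- sc$grids
  dfs <- disease_free_solve(p, g)
  Q0 <- q_lambda(p, g, 0)
  r <- spectral_radius_weighted(dfs$S_star, Q0)
  expect_equal(r$radius, 2, tolerance = 2e-4)      # R0 = r(S~ Q^0)
  expect_true(all(r$vector >= 0))
  r3 <- spectral_radius_weighted(3 * dfs$S_star, Q0)
  expect_equal(r3$radius, 3 * r$radius, tolerance = 1e-9)
})

test_that("radius curve decreases strictly with the expected limits", {
  sc <- fix_hom(2, nx = 15L, K = 30L)
  dfs <- disease_free_solve(sc$params, sc$grids)
  rc <- radius_curve(sc$params, sc$grids, dfs$S_star, c(-20, -1, 0, 1, 2, 20))
  expect_true(all(diff(rc$radius) < 0))
  expect_gt(rc$radius[1], 10)                      # lambda -> -inf blow-up
  expect_lt(rc$radius[6], 0.1)                     # lambda -> +inf decay
})

test_that("spectral bound: threshold identity and sign dichotomy", {
  g <- model_grids(hom_params(b = 1), nx = 15L, K = 60L)
  bound_for <- function(R0) {
    sc <- make_scenario(R0, nx = 15L, K = 60L)
    dfs <- disease_free_solve(sc$params, sc$grids)
    list(p = sc$params, g = sc$grids,
         s = spectral_bound(sc$params, sc$grids, dfs$S_star))
  }
  lo <- bound_for(0.8); hi <- bound_for(1.2)
  expect_lt(lo$s, 0)
  expect_gt(hi$s, 0)
  ## at the computed bound the defining identity r(S~ Q^s) = 1 holds
  dfs <- disease_free_solve(hi$p, hi$g)
  r_at_s <- spectral_radius_weighted(dfs$S_star,
                                     q_lambda(hi$p, hi$g, hi$s))$radius
  expect_equal(r_at_s, 1, tolerance = 1e-7)
  ## R0 tuned to 1: bound consistent with the closed-form crossing
  one <- bound_for(1)
  expect_lt(abs(one$s), 1e-3)
  ## shifting m upward decreases the bound
  p_up <- hom_params(kappa1 = 1, kappa2 = 1, m = 0.8, b = hi$p$b(0), a_m = 2)
  dfs_up <- disease_free_solve(p_up, hi$g)
  expect_lt(spectral_bound(p_up, hi$g, dfs_up$S_star), hi$s)
})

test_that("Volterra renewal solver: null input, first step, positivity", {
  sc <- fix_hom(0.8, nx = 11L, K = 20L)
  p <- sc$params; g <- sc$grids
  dfs <- disease_free_solve(p, g)
  z <- volterra_renewal_solve(p, g, dfs, rep(0, 11), matrix(0, 21, 11), 1)
  expect_equal(max(abs(z$B)), 0)
  ## initial infecteds concentrated at age zero: hand-evaluated first value
  I0 <- matrix(0, 21, 11); I0[1, ] <- 1
  vb <- volterra_renewal_solve(p, g, dfs, rep(0, 11), I0, 1)
  expect_equal(vb$B[1, ],
               dfs$S_star * p$b(0) * g$age$wa[1], tolerance = 1e-12)
  expect_true(all(vb$B >= 0))
})

test_that("Volterra route agrees with the matrix exponential of the
           uncoupled linearized generator at first order", {
  err_at <- function(K) {
    sc <- fix_hom(2, nx = 11L, K = K)
    p <- sc$params; g <- sc$grids
    es <- endemic_state(p, g)
    es <- endemic_residual(p, g, es$S_star, es$I_star[1, ])
    lin <- linearization_matrix(p, g, es)
    nx <- g$space$nx
    ## drop the bounded S-row coupling (-P* + N): that perturbation is not
    ## part of the semigroup the renewal equation represents
    wa <- g$age$wa
    bk <- vapply(seq_along(g$age$a), function(k) rep(p$b(g$age$a[k]), nx),
                 numeric(nx))
    q_star <- colSums(wa * t(bk) * es$I_star)
    A <- lin$A
    A[1:nx, ] <- 0
    A[1:nx, 1:nx] <- p$d1 * laplacian_matrix(g$space) +
      Matrix::Diagonal(nx, p$kappa1 - 2 * p$kappa1 * es$S_star / p$kappa2 -
                         q_star)
    X <- g$space$X[, 1]
    S0 <- 0.01 * cos(pi * X)
    I0 <- outer(exp(-g$age$a), 0.01 * (1 + 0.3 * cos(pi * X)))
    vb <- volterra_renewal_solve(p, g, es, S0, I0, 1)
    u0 <- c(S0, as.vector(t(I0[-1, , drop = FALSE])))
    uT <- as.numeric(Matrix::expm(1 * A) %*% u0)
    S_T <- uT[1:nx]
    I_T <- matrix(uT[-(1:nx)], ncol = nx, byrow = TRUE)
    den <- 1 - wa[1] * bk[, 1] * es$S_star
    rest <- colSums(wa[-1] * t(bk[, -1]) * I_T)
    I0_lin <- (q_star * S_T + es$S_star * rest) / den
    max(abs(vb$B[nrow(vb$B), ] - I0_lin))
  }
  e1 <- err_at(20L); e2 <- err_at(40L)
  expect_lt(e2, 1e-4)
  expect_equal(e1 / e2, 2, tolerance = 0.5)   # first-order agreement
})
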