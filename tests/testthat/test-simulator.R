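test_that("step preconditions: characteristic alignment and positivity", {
  sc <- fix_hom(2, nx = 11L, K = 10L)
  st <- initial_state(sc)
  expect_error(sim_step(st, sc$params, sc$grids, dt = 0.01),
               "characteristic alignment")
  bad <- st; bad$S[1] <- -0.1
  expect_error(sim_step(bad, sc$params, sc$grids), "negative")
})

test_that("analytic steady states are discrete fixed points", {
  sc <- fix_hom(2, nx = 15L, K = 30L)
  p <- sc$params; g <- sc$grids
  nx <- g$space$nx; K1 <- g$age$K + 1L
  ## trivial
  st0 <- population_state(0, rep(0, nx), matrix(0, K1, nx))
  st1 <- sim_step(st0, p, g)
  expect_equal(st1$S, st0$S)
  expect_equal(st1$I, st0$I)
  ## disease-free (kappa2, 0)
  std <- population_state(0, rep(p$kappa2, nx), matrix(0, K1, nx))
  std1 <- sim_step(std, p, g)
  expect_equal(std1$S, std$S, tolerance = 1e-13)
  ## endemic, constructed with the grid quadrature: fixed point to round-off
  es <- endemic_state(p, g)
  ste <- population_state(0, es$S_star, es$I_star)
  ste1 <- sim_step(ste, p, g)
  expect_lt(max(abs(ste1$S - ste$S)), 1e-12)
  expect_lt(max(abs(ste1$I - ste$I)), 1e-12)
})

test_that("positivity is preserved along trajectories", {
  sc <- fix_hom(3, nx = 15L, K = 25L)
  tr <- simulate_model(sc$params, sc$grids, initial_state(sc), 10,
                       save_every = 5L)
  mins <- vapply(tr$states, function(s) min(s$S, s$I), 0)
  expect_true(all(mins >= -1e-12))
})

test_that("spatially homogeneous Neumann runs match the space-free
           reduction computed by an independent MOL/RK2 solver", {
  sc <- fix_hom(2, nx = 9L, K = 50L)
  p <- sc$params; g <- sc$grids
  nx <- g$space$nx
  S0 <- 0.8 * p$kappa2
  I0f <- function(a) 0.1 * exp(-a)
  st <- population_state(0, rep(S0, nx), outer(I0f(g$age$a), rep(1, nx)))
  tr <- simulate_model(p, g, st, 4, save_every = 100L)
  fin <- tr$states[[length(tr$states)]]
  ## spatial homogeneity is preserved
  expect_lt(max(apply(fin$I, 1, function(r) diff(range(r)))), 1e-12)
  orac <- oracle_spacefree(p, S0, I0f, 4)
  expect_equal(fin$S[1], orac$S, tolerance = 0.02)
  expect_equal(sum(g$age$wa * fin$I[, 1]), sum(orac$wa * orac$I),
               tolerance = 0.05)
})

test_that("self-convergence is first order in dt = da", {
  run <- function(K) {
    sc <- fix_hom(2, nx = 11L, K = K)
    st <- initial_state(sc)
    tr <- simulate_model(sc$params, sc$grids, st, 2, save_every = 10 * K)
    fin <- tr$states[[length(tr$states)]]
    c(fin$S[1], total_infected(fin, sc$grids))
  }
  v1 <- run(25L); v2 <- run(50L); v4 <- run(100L)
  r <- abs(v1 - v2) / abs(v2 - v4)
  expect_gt(min(r), 1.5)          # ~2 for first order
  expect_lt(max(r), 3)
})

test_that("subcritical Neumann runs converge to (kappa2, 0)", {
  sc <- fix_hom(0.8, nx = 15L, K = 30L)
  tr <- simulate_model(sc$params, sc$grids, initial_state(sc), 80,
                       save_every = 1000L)
  fin <- tr$states[[length(tr$states)]]
  expect_lt(max(abs(fin$S - sc$params$kappa2)), 1e-6)
  expect_lt(max(fin$I), 1e-6)
})

test_that("small perturbations of the endemic state decay for 1 < R0 < 3", {
  sc <- fix_hom(2, nx = 15L, K = 30L)
  es <- endemic_state(sc$params, sc$grids)
  pert <- 1 + 0.01 * cos(pi * sc$grids$space$X[, 1])
  st <- population_state(0, es$S_star * pert,
                         es$I_star * rep(pert, each = nrow(es$I_star)))
  dist <- function(s) max(abs(s$S - es$S_star)) + max(abs(s$I - es$I_star))
  tr <- simulate_model(sc$params, sc$grids, st, 30, save_every = 150L)
  d <- vapply(tr$states, dist, 0)
  expect_lt(d[length(d)], d[1] / 100)
})

test_that("Dirichlet with kappa1 < mu0 drives S to extinction", {
  p <- model_params(kappa1 = pi^2 / 2, kappa2 = 1, m = 0.5, b = 0.5,
                    a_m = 2, L = 1, delta = 0)
  g <- model_grids(p, nx = 15L, K = 20L)
  st <- population_state(0, 0.3 * sin(pi * g$space$X[, 1]),
                         matrix(0.01, g$age$K + 1L, g$space$nx))
  tr <- simulate_model(p, g, st, 8, save_every = 100L)
  S_norms <- vapply(tr$states, function(s) max(s$S), 0)
  expect_lt(S_norms[length(S_norms)], 1e-8)
  expect_true(all(diff(S_norms) <= 1e-12))
})

test_that("mass balance: exact when nothing flows, first order in general", {
  ## disease-free rest state with m = r = 0: machine-zero residual
  p0 <- hom_params(kappa1 = 1, kappa2 = 1, m = 0, r = 0, b = 1, a_m = 2)
  g0 <- model_grids(p0, nx = 11L, K = 15L)
  st <- population_state(0, rep(1, 11), matrix(0, 16, 11))
  tr0 <- simulate_model(p0, g0, st, 0.5)
  expect_lt(max(abs(mass_balance_residual(tr0, p0, g0))), 1e-12)
  ## Dirichlet runs are rejected
  pd <- model_params(kappa1 = 1, kappa2 = 1, m = 0.5, b = 1, a_m = 2,
                     L = 1, delta = 0)
  gd <- model_grids(pd, nx = 11L, K = 15L)
  trd <- simulate_model(pd, gd,
                        population_state(0, rep(0.1, 11),
                                         matrix(0.01, 16, 11)), 0.2)
  expect_error(mass_balance_residual(trd, pd, gd), "Neumann")
  ## generic run: residual at a fixed time halves under dt-halving
  res_at <- function(K) {
    sc <- fix_hom(2, nx = 11L, K = K)
    tr <- simulate_model(sc$params, sc$grids, initial_state(sc), 1)
    r <- mass_balance_residual(tr, sc$params, sc$grids)
    abs(r[length(r)])
  }
  r1 <- res_at(25L); r2 <- res_at(50L)
  expect_equal(r1 / r2, 2, tolerance = 0.4)
})

test_that("logistic comparison bound dominates S", {
  ## S0 = kappa2, I0 = 0: z and S both constant at kappa2
  p <- hom_params(kappa1 = 1, kappa2 = 1, m = 0.5, r = 0, b = 1, a_m = 2)
  g <- model_grids(p, nx = 11L, K = 15L)
  st <- population_state(0, rep(1, 11), matrix(0, 16, 11))
  chk <- logistic_upper_bound_check(simulate_model(p, g, st, 1), p)
  expect_true(chk$ok)
  ## ||S0|| < kappa2: z increases to kappa2 and dominates
  sc <- fix_hom(1.5, nx = 15L, K = 25L)
  tr <- simulate_model(sc$params, sc$grids, initial_state(sc), 10,
                       save_every = 10L)
  chk2 <- logistic_upper_bound_check(tr, sc$params)
  expect_true(chk2$ok)
  ## the production cap sup_{S>=0} kappa1(1 - S/kappa2)S = kappa1 kappa2 / 4
  p2 <- hom_params(kappa1 = 1.3, kappa2 = 2.7, b = 1)
  opt <- stats::optimize(function(S) logistic_production(p2, S),
                         c(0, 10), maximum = TRUE, tol = 1e-10)
  expect_equal(opt$objective, 1.3 * 2.7 / 4, tolerance = 1e-9)
  ## r != 0 is rejected
  pr <- hom_params(kappa1 = 1, kappa2 = 1, m = 0.5, r = 0.1, b = 1, a_m = 2)
  gr <- model_grids(pr, nx = 11L, K = 15L)
  trr <- simulate_model(pr, gr, st, 0.5)
  expect_error(logistic_upper_bound_check(trr, pr), "r == 0")
})
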