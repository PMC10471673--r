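test_that("characteristic integral: normalization and bounds", {
  p <- make_scenario(2, nx = 11L, K = 10L)$params
  ## R(0, 0) = r0 * R0 = 1
  expect_equal(Re(char_R(p, 0, 0)), 1, tolerance = 1e-10)
  expect_equal(Im(char_R(p, 0, 0)), 0)
  ## |R(lambda, mu)| <= R(Re lambda, 0) <= 1 for Re lambda >= 0
  set.seed(41)
  lam <- complex(real = runif(25, 0, 5), imaginary = runif(25, -30, 30))
  mus <- runif(25, 0, 50)
  for (i in seq_along(lam)) {
    expect_lte(Mod(char_R(p, lam[i], mus[i])),
               Re(char_R(p, Re(lam[i]), 0)) + 1e-12)
    expect_lte(Re(char_R(p, Re(lam[i]), 0)), 1 + 1e-12)
  }
  ## dominated decay in mu, down to the age-zero quadrature floor
  floor0 <- 0.001 / 2 * (1 / 2) * p$kappa2 * p$b(0)  # wa_0 r0 k2 b(0), n=2001
  expect_lt(Mod(char_R(p, 1 + 1i, 1e4)), 2 * floor0)
  expect_lt(Mod(char_R(p, 1 + 1i, 1e4)), Mod(char_R(p, 1 + 1i, 100)))
  expect_error(char_R(make_scenario(0.8)$params, 0, 0), "R0 > 1")
})

test_that("the algebraic inequality behind the (1, 3) stability window", {
  ## |1 - (1-r0)/(zeta+r0)|^2 - 1 = (r0-1)(2a+3r0-1)/((a+r0)^2+b^2) < 0
  ## for zeta = a + ib with a >= 0 and 1/3 < r0 < 1
  set.seed(43)
  for (i in 1:200) {
    r0 <- runif(1, 1 / 3 + 1e-6, 1 - 1e-6)
    al <- runif(1, 0, 10); be <- runif(1, -20, 20)
    zeta <- complex(real = al, imaginary = be)
    lhs <- Mod(1 - (1 - r0) / (zeta + r0))^2 - 1
    rhs <- (r0 - 1) * (2 * al + 3 * r0 - 1) / ((al + r0)^2 + be^2)
    expect_equal(lhs, rhs, tolerance = 1e-10)
    expect_lt(lhs, 0)
  }
})

test_that("characteristic roots: none in the right half plane for R0 in
           (1,3); no real root on the nonnegative axis; conjugate pairs", {
  for (R0 in c(2, 2.9)) {
    p <- make_scenario(R0, nx = 11L, K = 10L)$params
    for (mu in c(0, pi^2)) {
      cr <- characteristic_roots(p, mu, re_lim = c(0, 10),
                                 im_lim = c(-50, 50))
      expect_identical(nrow(cr), 0L)
    }
  }
  ## real-axis scan: F real and of one sign for lambda >= 0
  p <- make_scenario(2, nx = 11L, K = 10L)$params
  lam <- seq(0, 10, length.out = 400)
  Fv <- Re(1 - char_R(p, lam, 0) *
             (1 - (1 - 0.5) / (lam / p$kappa1 + 0.5)))
  expect_true(all(Fv > 0) || all(Fv < 0))
  ## in a left-extended region the rightmost pair exists and is conjugate
  cr <- characteristic_roots(p, 0, re_lim = c(-1.2, 0.5),
                             im_lim = c(-20, 20))
  expect_gt(nrow(cr), 0)
  expect_true(all(cr$residual < 1e-9))
  for (i in seq_len(nrow(cr))) {
    j <- which.min(abs(cr$re - cr$re[i]) + abs(cr$im + cr$im[i]))
    expect_lt(abs(cr$im[j] + cr$im[i]), 1e-8)
  }
})

test_that("trivial-state classification follows sign(kappa1 - mu0)", {
  scn <- fix_hom(2, nx = 15L, K = 10L)
  expect_identical(classify_trivial(scn$params, scn$grids)$verdict,
                   "linearly_unstable")        # Neumann: mu0 = 0
  gd <- model_grids(model_params(kappa1 = 1, kappa2 = 1, b = 1, a_m = 2,
                                 L = 1, delta = 0), nx = 31L, K = 10L)
  mu0 <- laplacian_eigenpairs(gd$space, 1L)$values[1]
  mk <- function(k1) model_params(kappa1 = k1, kappa2 = 1, m = 0.5, b = 1,
                                  a_m = 2, L = 1, delta = 0)
  expect_identical(classify_trivial(mk(mu0 / 2), gd)$verdict,
                   "linearly_stable")
  expect_identical(classify_trivial(mk(mu0), gd)$verdict, "inconclusive")
})

test_that("disease-free classification matches the R0 dichotomy with
           consistent spectral-bound sign", {
  lo <- fix_hom(0.8, nx = 15L, K = 40L)
  rep_lo <- classify_disease_free(lo$params, lo$grids)
  expect_identical(rep_lo$verdict, "linearly_stable")
  expect_lt(rep_lo$evidence$spectral_bound, 0)
  hi <- fix_hom(1.2, nx = 15L, K = 40L)
  rep_hi <- classify_disease_free(hi$params, hi$grids)
  expect_identical(rep_hi$verdict, "linearly_unstable")
  expect_gt(rep_hi$evidence$spectral_bound, 0)
  expect_length(rep_hi$notes, 0)
})

test_that("endemic classification: stable inside the proven window,
           flagged beyond it", {
  rep2 <- classify_endemic(make_scenario(2, nx = 11L, K = 10L)$params)
  expect_identical(rep2$verdict, "linearly_stable")
  expect_length(rep2$notes, 0)
  rep29 <- classify_endemic(make_scenario(2.9, nx = 11L, K = 10L)$params)
  expect_identical(rep29$verdict, "linearly_stable")
  rep5 <- classify_endemic(make_scenario(5.5, nx = 11L, K = 10L)$params)
  expect_match(paste(rep5$notes, collapse = " "), "conjectural")
  expect_identical(rep5$verdict, "linearly_unstable")
})

test_that("linearization matrix: trivial state reproduces kappa1 - mu0 and
           eigenvectors satisfy the eigenvalue equation", {
  p <- model_params(kappa1 = 2, kappa2 = 1, m = 0.5, b = 1, a_m = 2,
                    L = 1, delta = 0)
  g <- model_grids(p, nx = 15L, K = 15L)
  lin <- linearization_matrix(p, g, trivial_state(g))
  ev <- rightmost_eigenvalues(lin, 1L)
  mu0 <- laplacian_eigenpairs(g$space, 1L)$values[1]
  expect_equal(Re(ev[1]), p$kappa1 - mu0, tolerance = 1e-9)
  expect_equal(Im(ev[1]), 0, tolerance = 1e-9)
  ## residual of the eigen equation for the rightmost pair
  e <- eigen(as.matrix(lin$A))
  i <- which.max(Re(e$values))
  expect_lt(max(Mod(as.matrix(lin$A) %*% e$vectors[, i] -
                      e$values[i] * e$vectors[, i])), 1e-8)
})

test_that("linearization matrix rejects non-steady states", {
  sc <- fix_hom(2, nx = 11L, K = 10L)
  bad <- endemic_residual(sc$params, sc$grids, rep(0.9, 11), rep(0.4, 11))
  expect_error(linearization_matrix(sc$params, sc$grids, bad), "not steady")
})

test_that("endemic linearization matches the characteristic roots at the
           discretization order (oracle equivalence)", {
  sc <- fix_hom(2, nx = 21L, K = 40L)
  p <- sc$params; g <- sc$grids
  es <- endemic_state(p, g)
  es <- endemic_residual(p, g, es$S_star, es$I_star[1, ])
  lin <- linearization_matrix(p, g, es)
  ev <- rightmost_eigenvalues(lin, 2L)
  mus <- laplacian_eigenpairs(g$space, 2L)$values
  cr <- do.call(rbind, lapply(mus, function(mu) {
    characteristic_roots(p, mu, re_lim = c(-1.2, 0.5), im_lim = c(-20, 20))
  }))
  i <- which.max(cr$re)
  tol <- 0.5 * (g$age$da + g$space$dx[1]^2)
  expect_lt(abs(Re(ev[1]) - cr$re[i]), tol)
  expect_lt(abs(abs(Im(ev[1])) - abs(cr$im[i])), tol)
})

test_that("disease-free linearization changes stability across R0 = 1", {
  right_eig <- function(R0) {
    sc <- fix_hom(R0, nx = 11L, K = 20L)
    dfs <- disease_free_solve(sc$params, sc$grids)
    lin <- linearization_matrix(sc$params, sc$grids, dfs)
    Re(rightmost_eigenvalues(lin, 1L)[1])
  }
  expect_lt(right_eig(0.85), 0)
  expect_gt(right_eig(1.2), 0)
})
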