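## Steady states of the model:
##   trivial       (0, 0)
##   disease-free  (S~, 0)  with  -Lap S~ + (kappa1/kappa2) S~^2 = kappa1 S~,
##                 which has a positive solution iff kappa1 > mu0
##                 (S~ = kappa2 under Neumann conditions)
##   endemic       (S*, I*), I* != 0, characterized through I0 := I*(0) by
##                 -Lap S* + (Q^0 I0) S* + (kappa1/kappa2) S*^2 = kappa1 S*
##                 and I0 = S* Q^0 I0; explicit for homogeneous Neumann data,
##                 nonexistent when R0 <= 1.

new_steady_state <- function(kind, S_star, I_star, R0 = NA_real_,
                             ages = NULL, grids = NULL,
                             residual_S = NA_real_, residual_I = NA_real_) {
  structure(list(kind = kind, S_star = S_star, I_star = I_star, R0 = R0,
                 ages = ages, grids = grids,
                 residual_S = residual_S, residual_I = residual_I),
            class = "steady_state")
}

#' @exportS3Method base::print
print.steady_state <- function(x, ...) {
  cat(sprintf("<steady_state: %s>\n", x$kind))
  cat(sprintf("  max S* = %g, max I* = %g\n",
              max(x$S_star), max(x$I_star)))
  if (!is.na(x$R0)) cat(sprintf("  R0 = %g\n", x$R0))
  if (!is.na(x$residual_S)) {
    cat(sprintf("  residuals: S %.3e, I %.3e\n", x$residual_S, x$residual_I))
  }
  invisible(x)
}

#' Trivial steady state
#'
#' @param grids grids from [model_grids()].
#' @return A `steady_state` of kind `"trivial"` (all zero).
#' @export
trivial_state <- function(grids) {
  new_steady_state("trivial",
                   S_star = rep(0, grids$space$nx),
                   I_star = matrix(0, grids$age$K + 1L, grids$space$nx))
}

## Damped Newton for -Lap S + diag(q) S + (kappa1/kappa2) S^2 = kappa1 S
## with Armijo backtracking on the residual norm and a positivity floor.
semilinear_newton <- function(Lh, q, kappa1, kappa2, S_init, w,
                              tol = 1e-10, max_iter = 100L, floor = 1e-14) {
  S <- pmax(S_init, floor)
  scale <- max(kappa1 * max(S_init), 1)
  G <- function(S) as.numeric(-Lh %*% S) + q * S + kappa1 / kappa2 * S^2 -
    kappa1 * S
  hist <- grid_norm2(G(S), w) / scale
  for (it in seq_len(max_iter)) {
    if (hist[length(hist)] < tol) {
      return(list(S = S, residual = hist[length(hist)], iterations = it - 1L,
                  history = hist, converged = TRUE))
    }
    res <- G(S)
    J <- -Lh + Matrix::Diagonal(length(S), q + 2 * kappa1 / kappa2 * S - kappa1)
    step <- as.numeric(Matrix::solve(J, res))
    t_ls <- 1
    repeat {
      S_new <- pmax(S - t_ls * step, floor)
      r_new <- grid_norm2(G(S_new), w) / scale
      if (r_new <= (1 - 1e-4 * t_ls) * hist[length(hist)] || t_ls < 1e-8) break
      t_ls <- t_ls / 2
    }
    if (t_ls < 1e-8 && r_new >= hist[length(hist)]) {
      return(list(S = S, residual = hist[length(hist)], iterations = it,
                  history = hist, converged = FALSE))
    }
    S <- S_new
    hist <- c(hist, r_new)
  }
  list(S = S, residual = hist[length(hist)], iterations = max_iter,
       history = hist, converged = hist[length(hist)] < tol)
}

#' Disease-free steady state
#'
#' Solves the discretized semilinear equation
#' `-Lap S + (kappa1/kappa2) S^2 = kappa1 S` for its unique positive
#' solution. A positive solution exists iff `kappa1 > mu0`, the principal
#' Laplacian eigenvalue; under Neumann conditions the solution is the
#' constant `kappa2` (returned directly). Otherwise a damped Newton
#' iteration is started from `kappa2` times the positively normalized
#' principal eigenvector.
#'
#' @param params a [model_params()].
#' @param grids grids from [model_grids()].
#' @param S_init optional Newton starting point (vector over nodes).
#' @param tol scaled residual tolerance.
#' @return A `steady_state` of kind `"disease_free"` (with `I_star = 0`).
#' @export
disease_free_solve <- function(params, grids, S_init = NULL, tol = 1e-10) {
  sg <- grids$space
  Z <- matrix(0, grids$age$K + 1L, sg$nx)
  if (params$delta == 1) {
    return(new_steady_state("disease_free",
                            S_star = rep(params$kappa2, sg$nx), I_star = Z,
                            grids = grids, residual_S = 0, residual_I = 0))
  }
  pe <- principal_eigenvalue(sg, 0)
  mu0 <- pe$value
  if (params$kappa1 <= mu0) {
    stop("no positive disease-free state: kappa1 = ", format(params$kappa1),
         " <= mu0 = ", format(mu0))
  }
  Lh <- laplacian_matrix(sg)
  if (is.null(S_init)) {
    ## Galerkin amplitude along the principal eigenfunction: for S = A phi,
    ## projecting the semilinear equation on phi gives
    ## A = (kappa1 - mu0) kappa2 <phi^2> / (kappa1 <phi^3>).
    phi <- pe$vector
    A <- (params$kappa1 - mu0) * params$kappa2 * sum(sg$w * phi^2) /
      (params$kappa1 * sum(sg$w * phi^3))
    S_init <- A * phi
  }
  sol <- NULL
  for (scale in c(1, 0.5, 2, 0.25, 4)) {
    cand <- semilinear_newton(Lh, rep(0, sg$nx), params$kappa1,
                              params$kappa2, scale * S_init, sg$w, tol = tol)
    ## reject collapse onto the trivial root
    if (cand$converged && max(cand$S) > 1e-6 * params$kappa2) {
      sol <- cand
      break
    }
  }
  if (is.null(sol)) {
    stop("Newton did not converge to a positive solution from the ",
         "eigenfunction initial guess (kappa1 = ", format(params$kappa1),
         ", mu0 = ", format(mu0), ")")
  }
  new_steady_state("disease_free", S_star = sol$S, I_star = Z, grids = grids,
                   residual_S = sol$residual, residual_I = 0)
}

#' Residuals of the endemic steady-state system
#'
#' Given a candidate susceptible field `S_star` and age-zero infected
#' profile `I0`, evaluates the discrete residual norms of the coupled
#' system `-Lap S* + (Q^0 I0) S* + (kappa1/kappa2) S*^2 = kappa1 S*` and
#' `I0 = S* Q^0 I0`, and reconstructs the full infected field
#' `I*(a) = U_A(a, 0) I0` for reporting.
#'
#' @inheritParams disease_free_solve
#' @param S_star candidate susceptible field.
#' @param I0 candidate age-zero infected profile.
#' @return A `steady_state` of kind `"endemic"` carrying `residual_S`
#'   and `residual_I` (grid 2-norms).
#' @export
endemic_residual <- function(params, grids, S_star, I0) {
  sg <- grids$space
  Lh <- laplacian_matrix(sg)
  Q0 <- q_lambda(params, grids, 0)
  q0I <- as.numeric(Q0$matrix %*% I0)
  res_S_vec <- as.numeric(-Lh %*% S_star) + q0I * S_star +
    params$kappa1 / params$kappa2 * S_star^2 - params$kappa1 * S_star
  res_I_vec <- I0 - S_star * q0I
  P <- evolution_sweep(params, grids)
  I_star <- t(vapply(P, function(Pk) as.numeric(Pk %*% I0),
                     numeric(sg$nx)))
  new_steady_state("endemic", S_star = S_star, I_star = I_star,
                   grids = grids,
                   residual_S = grid_norm2(res_S_vec, sg$w),
                   residual_I = grid_norm2(res_I_vec, sg$w))
}

## S*(I0): positive solution of the S equation given the infection pressure
## Q^0 I0 (exists when lambda_0(Q^0 I0) < kappa1).
solve_S_given_I0 <- function(params, grids, q0I, S_init) {
  sg <- grids$space
  lam0 <- principal_eigenvalue(sg, q0I)$value
  if (lam0 >= params$kappa1) {
    stop("no positive S branch: lambda_0(Q^0 I0) >= kappa1")
  }
  Lh <- laplacian_matrix(sg)
  sol <- semilinear_newton(Lh, q0I, params$kappa1, params$kappa2,
                           S_init, sg$w)
  if (!sol$converged) stop("S(I0) Newton did not converge")
  sol$S
}

#' Fixed-point collapse scan for subcritical parameters
#'
#' When `R0 <= 1` the model admits no endemic steady state. This scan runs
#' the fixed-point map `I0 -> S*(I0) Q^0 I0` from random positive starting
#' profiles and verifies that every iteration collapses to zero (sup norm
#' below `1e-10`), the discrete counterpart of the nonexistence result. The
#' scan refuses to run for `R0 > 1`, where existence is open in general.
#'
#' @inheritParams disease_free_solve
#' @param trials number of random starting profiles.
#' @param seed RNG seed (recorded in the report).
#' @param max_iter iteration cap per trial.
#' @return List with `R0`, `collapsed` (logical per trial), `final_sup`,
#'   `boundary_case` (`TRUE` when `R0` is within `1e-8` of 1), `seed`.
#' @export
endemic_nonexistence_scan <- function(params, grids, trials = 10L, seed = 1L,
                                      max_iter = 2000L) {
  sg <- grids$space
  dfs <- disease_free_solve(params, grids)
  family <- q_family(params, grids)
  Q0 <- q_lambda(params, grids, 0, family)
  R0 <- spectral_radius_weighted(dfs$S_star, Q0)$radius
  if (R0 > 1 + 1e-12) {
    stop("scan undefined for R0 = ", format(R0),
         " > 1 (endemic existence is open in the general case)")
  }
  set.seed(seed)
  final_sup <- numeric(trials)
  collapsed <- logical(trials)
  for (tr in seq_len(trials)) {
    I0 <- stats::runif(sg$nx, 0.5, 1.5)
    S <- dfs$S_star
    for (it in seq_len(max_iter)) {
      q0I <- as.numeric(Q0$matrix %*% I0)
      S <- solve_S_given_I0(params, grids, q0I, S)
      I0 <- S * q0I
      if (max(I0) < 1e-10) break
    }
    final_sup[tr] <- max(I0)
    collapsed[tr] <- final_sup[tr] < 1e-10
  }
  list(R0 = R0, collapsed = collapsed, final_sup = final_sup,
       boundary_case = abs(R0 - 1) < 1e-8, seed = seed, trials = trials)
}
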