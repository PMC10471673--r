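## Operator machinery for the linearized problem: the age-parameterized
## evolution operator U_A(a, sigma) of
##
##   dv/da = d(a) Lap v - (m(a,.) + r(a,.)) v,
##
## the next-generation family Q^lambda = int b(a) e^{-lambda a} U_A(a,0) da,
## the weighted spectral radius r(S* Q^lambda), the spectral bound (the real
## s with r(S* Q^s) = 1), and the Volterra renewal equation for the age-zero
## birth term of the linearized semigroup.
##
## Discretization mirrors the simulator exactly: one forward sweep over the
## age grid with an exponential decay factor and a backward-Euler diffusion
## solve per node, so the discrete generators of the simulator and of the
## spectral objects are consistent.

#' Apply the evolution operator U_A(a, sigma)
#'
#' Propagates a spatial field from infection age `sigma` to age `a` under
#' diffusion-with-decay, by sub-stepping with steps no larger than the age
#' spacing (exponential factor for the decay, backward Euler for the
#' diffusion). Positive inputs give positive outputs, and the grid 1-norm
#' does not increase when the mortality is nonnegative.
#'
#' @param params a [model_params()].
#' @param grids grids from [model_grids()].
#' @param a,sigma target and source infection ages, `0 <= sigma <= a <= a_m`.
#' @param v spatial field (vector over space nodes).
#' @return The propagated field.
#' @export
evolution_apply <- function(params, grids, a, sigma, v) {
  if (sigma > a) stop("need sigma <= a")
  if (a > params$a_m + 1e-12 || sigma < -1e-12) stop("ages must lie in [0, a_m]")
  if (a == sigma) return(v)
  sg <- grids$space
  Lh <- laplacian_matrix(sg)
  Id <- Matrix::Diagonal(sg$nx)
  nsub <- max(1L, ceiling((a - sigma) / grids$age$da - 1e-12))
  h <- (a - sigma) / nsub
  tau <- sigma + h * (0:nsub)
  mr <- vapply(tau, function(s) {
    eval_coef(params, "m", s, sg$X) + eval_coef(params, "r", s, sg$X)
  }, numeric(sg$nx))
  dk <- params$d(tau)
  out <- v
  fac <- NULL; d_prev <- NA_real_
  for (j in seq_len(nsub)) {
    decay <- exp(-h * (mr[, j] + mr[, j + 1L]) / 2)
    if (!identical(dk[j + 1L], d_prev)) {
      fac <- Matrix::Cholesky(
        methods::as(Id - h * dk[j + 1L] * Lh, "symmetricMatrix"), LDL = FALSE)
      d_prev <- dk[j + 1L]
    }
    out <- as.numeric(chol_solve(fac, decay * out))
  }
  out
}

## One forward age sweep of the evolution operator applied to the identity:
## P[[k]] approximates U_A(a_{k-1}, 0) as a dense nx x nx matrix.
evolution_sweep <- function(params, grids, prefab = NULL) {
  if (is.null(prefab)) prefab <- sim_prefab(params, grids)
  K <- prefab$K; nx <- prefab$nx
  P <- vector("list", K + 1L)
  P[[1L]] <- diag(nx)
  for (k in 2:(K + 1L)) {
    P[[k]] <- chol_solve(prefab$diff_fac[[k]],
                         prefab$decay[, k - 1L] * P[[k - 1L]])
  }
  P
}

## Age-weighted kernel blocks B_k = wa_k diag(b(a_k,.)) U_A(a_k, 0); the
## whole Q^lambda family is then a lambda-weighted sum of these blocks.
q_family <- function(params, grids, prefab = NULL) {
  if (is.null(prefab)) prefab <- sim_prefab(params, grids)
  P <- evolution_sweep(params, grids, prefab)
  blocks <- lapply(seq_along(P), function(k) {
    prefab$wa[k] * prefab$bk[, k] * P[[k]]
  })
  structure(list(blocks = blocks, a = grids$age$a, params_hash = NULL),
            class = "q_family")
}

#' Assemble the operator Q^lambda
#'
#' The discrete next-generation kernel
#' `Q^lambda = int_0^{a_m} b(a) e^{-lambda a} U_A(a, 0) da`, assembled by
#' trapezoid quadrature from one forward age sweep of the evolution
#' operator. For real `lambda` and nonnegative transmission the matrix is
#' entrywise nonnegative and entrywise decreasing in `lambda`.
#'
#' @inheritParams evolution_apply
#' @param lambda complex or real shift.
#' @param family optionally, a precomputed kernel family (internal reuse).
#' @return A `q_lambda` object with fields `lambda` and `matrix`.
#' @export
q_lambda <- function(params, grids, lambda = 0, family = NULL) {
  if (is.null(family)) family <- q_family(params, grids)
  wts <- exp(-lambda * family$a)
  M <- Reduce(`+`, Map(`*`, as.list(wts), family$blocks))
  structure(list(lambda = lambda, matrix = M, a = family$a),
            class = "q_lambda")
}

#' Weighted spectral radius r(S* Q^lambda)
#'
#' Spectral radius of `diag(S_star) %*% Q` by power iteration started in
#' the positive cone, with a convergence check on the Rayleigh quotient.
#' For an irreducible nonnegative kernel this is the Perron root and the
#' associated eigenvector is positive (checked).
#'
#' @param S_star nonnegative spatial weight (steady-state susceptibles).
#' @param Q a [q_lambda()] object with real `lambda`.
#' @param tol convergence tolerance on the Rayleigh quotient.
#' @param max_iter iteration cap.
#' @return List with `radius`, positive `vector`, and `iterations`.
#' @export
spectral_radius_weighted <- function(S_star, Q, tol = 1e-10,
                                     max_iter = 10000L) {
  if (is.complex(Q$lambda)) stop("spectral radius is defined for real lambda")
  if (any(S_star < 0) || all(S_star == 0)) {
    stop("S_star must be nonnegative and not identically zero")
  }
  M <- S_star * Q$matrix
  n <- nrow(M)
  v <- rep(1, n)
  rho <- 0
  history <- numeric(0)
  for (it in seq_len(max_iter)) {
    w <- as.numeric(M %*% v)
    nrm <- max(abs(w))
    if (nrm == 0) {
      return(list(radius = 0, vector = v / max(v), iterations = it))
    }
    rho_new <- sum(v * w) / sum(v * v)
    w <- w / nrm
    if (it > 1L && abs(rho_new - rho) <= tol * max(abs(rho_new), 1e-300)) {
      if (min(w) < -1e-8 * max(abs(w))) {
        warning("principal eigenvector of S* Q^lambda is not positive")
      }
      return(list(radius = rho_new, vector = pmax(w, 0), iterations = it))
    }
    rho <- rho_new
    v <- w
    history <- c(history, rho_new)
  }
  stop("power iteration did not converge; Rayleigh history tail: ",
       paste(format(utils::tail(history, 5)), collapse = ", "))
}

#' Spectral bound of the linearized infection semigroup
#'
#' The unique real `s` with `r(S_star Q^s) = 1`. The radius is continuous
#' and strictly decreasing in the shift, diverging as the shift goes to
#' minus infinity and vanishing at plus infinity, so the root is found by
#' bracketed bisection. Its sign equals the sign of `r(S_star Q^0) - 1`,
#' i.e. of `R0 - 1` at the disease-free state.
#'
#' @inheritParams q_lambda
#' @param S_star nonnegative spatial weight.
#' @param tol absolute tolerance on the bound.
#' @param s_max bracket expansion limit.
#' @param family optionally, a precomputed kernel family (internal reuse).
#' @return The spectral bound `s`.
#' @export
spectral_bound <- function(params, grids, S_star, tol = 1e-8, s_max = 1e3,
                           family = NULL) {
  if (is.null(family)) family <- q_family(params, grids)
  rho <- function(s) {
    spectral_radius_weighted(S_star, q_lambda(params, grids, s, family))$radius
  }
  lo <- -1; hi <- 1
  while (rho(hi) > 1) {
    hi <- hi * 2
    if (hi > s_max) stop("bracket expansion exceeded s_max")
  }
  while (rho(lo) < 1) {
    lo <- lo * 2
    if (lo < -s_max) stop("bracket expansion exceeded s_max")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (rho(mid) >= 1) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Sample the radius curve lambda -> r(S* Q^lambda)
#'
#' @inheritParams spectral_bound
#' @param lambdas real shifts to sample.
#' @return data.frame with columns `lambda` and `radius` (strictly
#'   decreasing in `lambda`).
#' @export
radius_curve <- function(params, grids, S_star, lambdas) {
  family <- q_family(params, grids)
  data.frame(
    lambda = lambdas,
    radius = vapply(lambdas, function(s) {
      spectral_radius_weighted(S_star,
                               q_lambda(params, grids, s, family))$radius
    }, 0))
}

#' Solve the Volterra renewal equation of the linearization
#'
#' Around a steady state `(S*, I*)`, the age-zero component `B(t)` of the
#' linearized infected field solves
#' `B(t) = S* int_0^t b(a) U_A(a,0) B(t-a) da + forcing(t; S0, I0)`,
#' where the forcing collects the transported initial infected profile and
#' the susceptible perturbation weighted by the steady infection pressure
#' `q* = int b I* da`. The kernel is lower triangular in time, so the
#' equation is solved by forward marching; the kernel quadrature uses a
#' left-rectangle weight at the first node (first-order accurate), which
#' keeps the marching explicit. Nonnegative inputs give nonnegative `B`.
#'
#' @inheritParams q_lambda
#' @param state a `steady_state` (supplies `S*`, `I*`, hence `q*` and the
#'   linearized susceptible generator).
#' @param S0 initial susceptible perturbation (vector over space nodes).
#' @param I0 initial infected perturbation (age-by-space matrix).
#' @param t_end time horizon (marched on the age/time grid).
#' @return List with `times` and `B` (time-by-space matrix).
#' @export
volterra_renewal_solve <- function(params, grids, state, S0, I0, t_end) {
  prefab <- sim_prefab(params, grids)
  sg <- grids$space; ag <- grids$age
  K <- ag$K; dt <- ag$da; nx <- sg$nx
  nsteps <- max(1L, round(t_end / dt))
  if (!is.matrix(I0)) I0 <- matrix(I0, ncol = nx)
  S_star <- state$S_star
  q_star <- colSums(ag$wa * t(prefab$bk) * state$I_star)
  ## kernel blocks at positive lags: dt * b(a_k) U_A(a_k, 0), k = 1..K
  P <- evolution_sweep(params, grids, prefab)
  kern <- lapply(2:(K + 1L), function(k) dt * prefab$bk[, k] * P[[k]])
  ## transported initial profile: for each starting age node j propagate
  ## I0(a_j) forward; column j at stage j+k is U_A(a_{j+k}, a_j) I0(a_j)
  prop <- t(I0)                            # nx x (K+1), current stage fields
  forcing_I <- matrix(0, nsteps + 1L, nx)
  wa <- ag$wa
  forcing_I[1L, ] <- colSums(wa * t(prefab$bk) * t(prop))
  for (s in seq_len(min(nsteps, K))) {
    live <- 1:(K + 1L - s)                 # starting nodes still below a_m
    for (j in live) {
      k <- j + s                           # arrival node index
      prop[, j] <- chol_solve(prefab$diff_fac[[k]],
                              prefab$decay[, k - 1L] * prop[, j])
    }
    prop[, setdiff(seq_len(K + 1L), live)] <- 0
    ## trapezoid over the surviving age range [0, a_m - t], with the
    ## arrival-age transmission weight b(a + t)
    w_live <- if (length(live) >= 2L) trapz_weights(length(live), dt) else dt
    bw <- prefab$bk[, live + s, drop = FALSE]
    forcing_I[s + 1L, ] <- colSums(w_live * t(bw) *
                                     t(prop[, live, drop = FALSE]))
  }
  ## susceptible forcing q* e^{t A1*} S0 by backward Euler on A1*
  Lh <- prefab$Lh
  react <- params$kappa1 - 2 * params$kappa1 * S_star / params$kappa2 - q_star
  M1 <- Matrix::Diagonal(nx) - dt * (params$d1 * Lh + Matrix::Diagonal(nx, react))
  lu1 <- Matrix::lu(M1)
  Svec <- S0
  B <- matrix(0, nsteps + 1L, nx)
  B[1L, ] <- S_star * forcing_I[1L, ] + q_star * Svec
  for (s in seq_len(nsteps)) {
    conv <- rep(0, nx)
    for (j in seq_len(min(s, K))) {
      conv <- conv + as.numeric(kern[[j]] %*% B[s + 1L - j, ])
    }
    Svec <- as.numeric(Matrix::solve(lu1, Svec))
    B[s + 1L, ] <- S_star * (conv + forcing_I[s + 1L, ]) + q_star * Svec
  }
  list(times = dt * (0:nsteps), B = B)
}
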