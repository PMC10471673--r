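## Time integration of the nonlinear model by the method of characteristics
## in (t, a) with Lie splitting:
##
##   (i)  transport: I(t+dt, a_k) is obtained from I(t, a_{k-1}) by an exact
##        exponential decay factor for the reaction -(m+r) I and a backward
##        Euler solve for the diffusion d(a_k) Lap I (an M-matrix solve,
##        hence unconditionally positivity preserving);
##   (ii) renewal: the age-zero value solves the trapezoid-discretized
##        boundary condition I(t+dt, 0) = S int b I da implicitly in its own
##        node (a per-node scalar equation);
##   (iii) the S equation takes the reaction explicitly and the diffusion by
##        backward Euler, with a runtime positivity check on the explicit
##        stage.
##
## The time step equals the age spacing (characteristic alignment), so age
## transport is exact and free of numerical dispersion.

#' Population state
#'
#' @param t time.
#' @param S susceptible density, vector over space nodes.
#' @param I infected density, matrix of age nodes by space nodes.
#' @return A `population_state` object.
#' @export
population_state <- function(t, S, I) {
  if (!is.matrix(I)) I <- matrix(I, ncol = length(S))
  if (ncol(I) != length(S)) stop("I must have one column per space node")
  if (any(!is.finite(S)) || any(!is.finite(I))) {
    stop("state contains non-finite values")
  }
  structure(list(t = t, S = S, I = I), class = "population_state")
}

## Precompute per-age-node transport factors and factorized diffusion
## solves; reused across all time steps and by the spectral module.
sim_prefab <- function(params, grids) {
  sg <- grids$space; ag <- grids$age
  Lh <- laplacian_matrix(sg)
  K <- ag$K; a <- ag$a; dt <- ag$da
  mr <- vapply(seq_len(K + 1L), function(k) {
    eval_coef(params, "m", a[k], sg$X) + eval_coef(params, "r", a[k], sg$X)
  }, numeric(sg$nx))                       # nx x (K+1)
  bk <- vapply(seq_len(K + 1L), function(k) {
    eval_coef(params, "b", a[k], sg$X)
  }, numeric(sg$nx))
  rk <- vapply(seq_len(K + 1L), function(k) {
    eval_coef(params, "r", a[k], sg$X)
  }, numeric(sg$nx))
  dk <- params$d(a)
  Id <- Matrix::Diagonal(sg$nx)
  diff_fac <- lapply(seq_len(K + 1L), function(k) {
    Matrix::Cholesky(methods::as(Id - dt * dk[k] * Lh, "symmetricMatrix"),
                     LDL = FALSE)
  })
  diff_fac_S <- Matrix::Cholesky(
    methods::as(Id - dt * params$d1 * Lh, "symmetricMatrix"), LDL = FALSE)
  ## decay along the characteristic from a_{k-1} to a_k (trapezoid average)
  decay <- exp(-dt * (mr[, -(K + 1L), drop = FALSE] +
                        mr[, -1L, drop = FALSE]) / 2)
  list(Lh = Lh, mr = mr, bk = bk, rk = rk, dk = dk, decay = decay,
       diff_fac = diff_fac, diff_fac_S = diff_fac_S, dt = dt,
       wa = ag$wa, nx = sg$nx, K = K)
}

chol_solve <- function(fac, rhs) {
  as.matrix(Matrix::solve(fac, rhs, system = "A"))
}

#' One time step of the simulator
#'
#' Advances the state by `dt`, which must equal the age spacing of the
#' grids. Nonnegative input states stay nonnegative provided the explicit
#' reaction stage of the S equation satisfies its step restriction, which is
#' checked at runtime.
#'
#' @param state a [population_state()].
#' @param params a [model_params()].
#' @param grids grids from [model_grids()].
#' @param dt time step; must equal `grids$age$da`.
#' @param prefab precomputed operators (internal; built when missing).
#' @return The advanced `population_state`.
#' @export
sim_step <- function(state, params, grids, dt = grids$age$da,
                     prefab = NULL) {
  if (abs(dt - grids$age$da) > 1e-12 * grids$age$da) {
    stop("dt must equal the age spacing (characteristic alignment)")
  }
  if (min(state$S) < 0 || min(state$I) < 0) {
    stop("negative input densities")
  }
  if (is.null(prefab)) prefab <- sim_prefab(params, grids)
  K <- prefab$K
  S <- state$S
  Inew <- state$I
  ## (i) transport with decay + implicit diffusion, oldest age first
  for (k in (K + 1L):2L) {
    Inew[k, ] <- chol_solve(prefab$diff_fac[[k]],
                            prefab$decay[, k - 1L] * state$I[k - 1L, ])
  }
  ## (ii) renewal, implicit in the age-zero node of the trapezoid rule:
  ## rest_x = sum_{k>=1} wa_k b_k(x) I_k(x)
  rest <- colSums(prefab$wa[-1L] * t(prefab$bk[, -1L, drop = FALSE]) *
                    Inew[-1L, , drop = FALSE])
  den <- 1 - S * prefab$wa[1L] * prefab$bk[, 1L]
  if (any(den <= 0)) {
    stop("renewal step lost diagonal dominance; decrease the time step")
  }
  Inew[1L, ] <- S * rest / den
  ## (iii) S reaction (explicit) + diffusion (implicit)
  int_bI <- colSums(prefab$wa * t(prefab$bk) * Inew)
  int_rI <- colSums(prefab$wa * t(prefab$rk) * Inew)
  growth <- 1 + dt * params$kappa1 * (1 - S / params$kappa2) - dt * int_bI
  if (any(growth < 0)) {
    stop("explicit reaction stage violates positivity; decrease the time step ",
         "(need dt * (kappa1 + ||b|| ||int I||) < 1)")
  }
  S_half <- S * growth + dt * int_rI
  Snew <- as.numeric(chol_solve(prefab$diff_fac_S, S_half))
  if (any(!is.finite(Snew)) || any(!is.finite(Inew))) {
    stop("non-finite values produced at t = ", state$t + dt)
  }
  population_state(state$t + dt, Snew, Inew)
}

#' Simulate the model
#'
#' Repeatedly applies [sim_step()] with time step equal to the age spacing
#' and records the state every `save_every` steps (the initial and final
#' states are always kept).
#'
#' @inheritParams sim_step
#' @param initial a [population_state()] at time 0.
#' @param t_end time horizon; rounded to a whole number of steps.
#' @param save_every save interval in steps.
#' @return A `trajectory` object: list with `times`, `states` and a
#'   `manifest` describing the run.
#' @export
simulate_model <- function(params, grids, initial, t_end, save_every = 1L) {
  prefab <- sim_prefab(params, grids)
  dt <- grids$age$da
  nsteps <- max(1L, round(t_end / dt))
  state <- initial
  times <- state$t
  states <- list(state)
  for (s in seq_len(nsteps)) {
    state <- sim_step(state, params, grids, dt, prefab)
    if (s %% save_every == 0L || s == nsteps) {
      times <- c(times, state$t)
      states[[length(states) + 1L]] <- state
    }
  }
  structure(list(times = times, states = states, params = params,
                 grids = grids,
                 manifest = list(dt = dt, nsteps = nsteps,
                                 save_every = save_every,
                                 scheme = "characteristics + backward-Euler diffusion")),
            class = "trajectory")
}

#' @exportS3Method base::print
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d saved states on t in [%g, %g], dt = %g\n",
              length(x$times), min(x$times), max(x$times), x$manifest$dt))
  invisible(x)
}

#' Mass-balance residual of a Neumann run
#'
#' For Neumann boundary conditions the total population obeys an exact
#' balance law: the change of `int S + int int I` equals logistic production
#' minus mortality losses minus the outflow of infected individuals reaching
#' the maximal infection age. This function evaluates the discrete residual
#' of that balance between consecutive saved states (save interval 1); it
#' vanishes at first order in the step size.
#'
#' @param traj a `trajectory` from a Neumann run with `save_every = 1`.
#' @param params,grids the run's parameters and grids.
#' @return Numeric vector of per-step residuals.
#' @export
mass_balance_residual <- function(traj, params, grids) {
  if (params$delta != 1) {
    stop("mass balance is an identity only for Neumann boundary conditions")
  }
  sg <- grids$space; ag <- grids$age
  dt <- ag$da
  wx <- sg$w
  K <- ag$K
  mmat <- vapply(seq_along(ag$a), function(k) {
    eval_coef(params, "m", ag$a[k], sg$X)
  }, numeric(sg$nx))                      # nx x (K+1)
  res <- numeric(length(traj$states) - 1L)
  ## left-rectangle age mass: the exact invariant of the characteristic
  ## shift (the age-zero inflow and the renewal loss of the S equation then
  ## cancel identically, as they do in the continuum balance)
  mass <- function(st) {
    sum(wx * st$S) + dt * sum(st$I[seq_len(K), , drop = FALSE] %*% wx)
  }
  for (i in seq_along(res)) {
    s0 <- traj$states[[i]]; s1 <- traj$states[[i + 1L]]
    if (abs(s1$t - s0$t - dt) > 1e-9) {
      stop("mass balance needs consecutive steps (save_every = 1)")
    }
    production <- sum(wx * logistic_production(params, s1$S))
    mortality <- dt * sum((s1$I[seq_len(K), , drop = FALSE] *
                             t(mmat)[seq_len(K), , drop = FALSE]) %*% wx)
    outflow <- sum(wx * s1$I[K + 1L, ])
    res[i] <- (mass(s1) - mass(s0)) / dt -
      (production - mortality - outflow)
  }
  res
}

#' Logistic comparison bound on S
#'
#' With no recovery (`r == 0`) and Neumann boundary conditions, the
#' susceptible density is dominated by the solution of the logistic equation
#' `z' = kappa1 (1 - z/kappa2) z` started from the supremum of the initial
#' susceptibles. Checks `max_x S(t, x) <= z(t) + tol` on all saved states.
#'
#' @param traj a `trajectory`.
#' @param params the run's parameters (must have `r == 0`).
#' @param tol additive tolerance for discretization error.
#' @return List with `ok` (logical) and `max_violation`.
#' @export
logistic_upper_bound_check <- function(traj, params, tol = 1e-8) {
  if (params$delta != 1) stop("comparison bound requires Neumann conditions")
  ab <- seq(0, params$a_m, length.out = 65L)
  rv <- if (inherits(params, "hom_params")) params$r(ab) else {
    vapply(ab, function(a) max(params$r(a, traj$grids$space$X)), 0)
  }
  if (any(rv != 0)) stop("comparison bound is proved for r == 0 only")
  z0 <- max(traj$states[[1L]]$S)
  k1 <- params$kappa1; k2 <- params$kappa2
  z <- function(t) {
    if (z0 == 0) return(rep(0, length(t)))
    k2 * z0 / (z0 + (k2 - z0) * exp(-k1 * t))
  }
  viol <- vapply(seq_along(traj$states), function(i) {
    max(traj$states[[i]]$S) - z(traj$times[i] - traj$times[1L])
  }, 0)
  list(ok = all(viol <= tol), max_violation = max(viol))
}
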