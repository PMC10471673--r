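---
title: "Methods: age-structured reaction–diffusion epidemics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-structured reaction–diffusion epidemics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agestructrd)
```

## The model and its assumptions

`agestructrd` analyzes a two-compartment epidemic model on a bounded
spatial domain in which the infected population is structured by infection
age $a \in [0, a_m]$:

$$
\begin{aligned}
\partial_t S &= d_1 \Delta S + \kappa_1\Big(1 - \tfrac{S}{\kappa_2}\Big) S
  - S \int_0^{a_m} b\, I \,\mathrm{d}a + \int_0^{a_m} r\, I \,\mathrm{d}a,\\
(\partial_t + \partial_a) I &= d(a) \Delta I - (m + r)\, I,\\
I(t, 0, x) &= S(t, x) \int_0^{a_m} b(a, x)\, I(t, a, x)\,\mathrm{d}a,
\end{aligned}
$$

with Dirichlet or Neumann boundary conditions. Standing assumptions,
enforced by the parameter constructors: $\kappa_1, \kappa_2 > 0$; the
infected diffusion coefficient $d(a)$ bounded below by a positive
constant; $m, r, b \ge 0$ with $b \not\equiv 0$ (strictly positive in the
homogeneous specialization). The continuous theory guarantees a unique
positive global solution; the package treats those consequences —
positivity, no blow-up, the three steady-state families — as testable
invariants of the discretization rather than theorems.

Two deliberate narrowings of the continuous setting:

* **Finite maximal age only.** The theory permits $a_m = \infty$; we
  require $a_m < \infty$ and leave truncation of long-tailed infectivity
  kernels to the user.
* **Intervals and rectangles only.** Every quantitative object used here
  (Laplacian spectrum, principal eigenvalues, per-mode characteristic
  equations) depends on the domain only through the Laplacian
  eigendecomposition, which intervals and rectangles (Kronecker sums)
  expose exactly. General smooth domains would add meshing machinery
  without exercising any new part of the analysis.
* **Piecewise-smooth coefficients.** The theory allows merely
  Hölder/essentially-bounded rates; the trapezoid quadratures assume
  piecewise smoothness. Genuinely rough coefficients would degrade the
  advertised quadrature accuracy silently, which is why the age
  quadratures carry Richardson consistency checks.

## Discretization

**Space.** Uniform second-order finite differences. Neumann grids are
cell-centered with ghost-node reflection (row sums of the Laplacian are
exactly zero, so the principal eigenvalue is exactly $\mu_0 = 0$ with
constant eigenvector); Dirichlet grids eliminate the boundary nodes
($\mu_0 > 0$). Eigenpairs are computed by dense symmetric LAPACK solves:
all problem sizes in this package stay below a few thousand unknowns, so
the iterative shift-invert branch a larger code would need was not built.
The grid inner product carries $\Delta x$ weights so normalizations
approximate $L^2(\Omega)$.

**Age and time.** Uniform age nodes with the simulator time step tied to
the age spacing, $\Delta t = \Delta a$. This makes age transport an exact
shift along characteristics (no numerical dispersion), the standard
escalator-boxcar alignment for renewal equations. One step is a Lie
splitting:

1. *transport*: cohort $k{-}1$ moves to node $k$, multiplied by the
   exponential integrating factor $\exp(-\Delta t\,\overline{m{+}r})$
   (trapezoid average along the characteristic — this makes the discrete
   survival curve exactly the cumulative-trapezoid $\Pi$, so the explicit
   endemic formula is a *machine-precision* fixed point of the scheme),
   then a backward Euler diffusion solve $(I - \Delta t\, d(a_k) L_h)^{-1}$.
   Both factors map nonnegative data to nonnegative data unconditionally
   (M-matrix); Crank–Nicolson was rejected for exactly this reason.
2. *renewal*: the age-zero node solves the trapezoid-discretized boundary
   condition implicitly in its own node (a scalar equation per grid
   point), keeping the quadrature consistent with every other age
   integral in the package.
3. *S update*: reaction explicit, diffusion backward Euler. The explicit
   stage has a genuine step restriction
   $\Delta t(\kappa_1 + \lVert b\rVert\,\lVert\int I\rVert) < 1$; it is
   checked per node at runtime and violation raises an error advising a
   smaller step, rather than silently clipping.

**Mass balance.** Under Neumann conditions the total population obeys an
exact balance (production − mortality − age-boundary outflow). The
diagnostic uses a *left-rectangle* age mass: that is the exact invariant
of the characteristic shift, so the residual is zero for pure transport
and $O(\Delta t)$ in general. With trapezoid weights the half-weight at
age zero leaves a non-vanishing artifact — a discretization-geometry
point, not a property of the model. The residual converges at first
order away from the initial layer; the first few steps after an
incompatible initial datum (one violating the renewal condition) carry a
larger, decaying residual, which is why convergence is measured at a
fixed positive time.

## Spectral objects

The evolution operator $U_A(a,\sigma)$ of
$\partial_a v = d(a)\Delta v - (m+r)v$ is discretized with the *same*
decay-then-implicit-diffusion sub-steps as the simulator, so the
simulator, the next-generation operator and the linearization share one
discrete generator. The kernel family
$Q^\lambda = \int b(a) e^{-\lambda a} U_A(a,0)\,\mathrm{d}a$ is assembled
from one forward age sweep applied to the identity; because the
$\lambda$-dependence is a scalar weight per age node, the entire
$\lambda$-family reuses a single sweep — this is what makes the nested
bisections of the acceptance computations affordable.

$r(S_* Q^\lambda)$ is computed by power iteration started at the positive
constant vector (tolerance $10^{-10}$ on the Rayleigh quotient), with the
positivity of the principal eigenvector checked as a Krein–Rutman
surrogate. The spectral bound solves $r(S_* Q^s) = 1$ by bracketed
bisection to $10^{-8}$; monotonicity and the two divergence limits of the
radius curve are property-tested rather than assumed.

Accuracy note: with backward Euler sub-steps the evolution operator is
first-order accurate. Two-level Richardson extrapolation removes the
$O(h)$ term; the $10^{-8}$ agreement with the homogeneous closed form
(decay factor times heat semigroup) is verified over the full age range,
where diffusion has damped every nonconstant Laplacian mode by
$e^{-2\pi^2}$ — over short age intervals the extrapolated error is larger
($O(h^2 \mu^3)$ per mode) and no such claim is made.

## Steady states

The disease-free equation
$-\Delta \tilde S + (\kappa_1/\kappa_2)\tilde S^2 = \kappa_1 \tilde S$ is
solved by damped Newton (Armijo backtracking on the residual norm,
positivity floor $10^{-14}$). Two non-obvious choices:

* the initial guess is the principal eigenfunction scaled by its
  *Galerkin amplitude* $(\kappa_1-\mu_0)\kappa_2\langle\phi^2\rangle /
  (\kappa_1\langle\phi^3\rangle)$ — starting at carrying-capacity
  amplitude sends Newton into the basin of the trivial root near the
  bifurcation point;
* a converged iterate with $\max \tilde S < 10^{-6}\kappa_2$ is treated as
  collapse onto the trivial solution and retried from rescaled starts,
  never returned.

Existence holds iff $\kappa_1 > \mu_0$, which the solver enforces as a
hard error. The computed state satisfies the principal-eigenvalue
identity $\lambda_0(\kappa_1\tilde S/\kappa_2) = \kappa_1$ to Newton
tolerance — used as a test, since it is exact for the discrete operator.

The general endemic *existence* problem is open in the theory and is not
solved here: the package only (a) evaluates residuals of candidate
endemic states against the discrete steady-state system, (b) returns the
explicit homogeneous-Neumann state, and (c) for $R_0 \le 1$ runs the
fixed-point map $I_0 \mapsto S_*(I_0) Q^0 I_0$ from seeded random starts
and verifies collapse to zero — the constructive counterpart of the
nonexistence result. The scan *refuses* $R_0 > 1$ rather than asserting
an answer there. At $R_0 = 1$ exactly the collapse is algebraic (the map
has unit linearization), so the boundary case is flagged and only a loose
decay is asserted.

## Stability classification

*Trivial state*: the rightmost spectral point is $\kappa_1 - \mu_0$
analytically; the verdict is its sign, with a $\pm 10^{-6}$ inconclusive
band (marginal cases are never classified).

*Disease-free state*: verdict from $\operatorname{sign}(R_0 - 1)$ with
the spectral bound as corroborating evidence; a sign disagreement between
the two would be reported in the output notes.

*Endemic state* (homogeneous Neumann): the linearization diagonalizes
over Laplacian modes $\mu_j$, giving per mode the scalar characteristic
equation
$$
\frac{1}{\mathcal R(\lambda,\mu_j)} = 1 -
\frac{1-r_0}{(\lambda+\mu_j)/\kappa_1 + r_0},
\qquad r_0 = 1/R_0 .
$$
Roots are counted by the argument principle on a rectangle boundary. Two
implementation points:

* the equation is first multiplied through by its denominator, giving an
  entire function — the single pole at $\lambda = -\kappa_1 r_0 - \mu_j$
  is removed analytically instead of being dodged geometrically;
* the boundary mesh (4096 points) is refined *adaptively* wherever a
  phase step exceeds $\pi/2$: a root just outside the contour (which
  really occurs near the stability boundary) otherwise corrupts the
  winding count.

Winding-positive rectangles are bisected until small, then roots are
polished by Newton with the analytic derivative (residuals $\sim 10^{-12}$,
far below the $10^{-9}$ acceptance bound on root residuals).

High modes are handled by a certificate instead of search: for
$\mathrm{Re}\,\lambda \ge 0$,
$|\mathcal R(\lambda,\mu)| \le \mathcal R(0,\mu)$ and the right-hand side
of the characteristic equation has modulus at most
$1 + (1-r_0)/(\mu/\kappa_1 + r_0)$; when the product of the two bounds is
below 1 no root exists at that mode, and both bounds decrease in $\mu$,
so one certified mode certifies the whole tail. On the reference family
every mode $j \ge 1$ is certified for all scanned $R_0$ — the root search
effectively concerns only the spatially constant mode, which is exactly
the non-diffusive age-structured reduction.

The independent cross-check is a sparse discrete linearization on the
stacked unknowns $(S, I_1,\dots,I_K)$: first-order upwind age transport
(matching the simulator, keeping the two discrete generators consistent),
the renewal constraint eliminated into the age-zero row, and the
$-P_* + N$ coupling in the $S$ row. Its rightmost eigenvalue agrees with
the rightmost characteristic root to $O(\Delta a + \Delta x^2)$, tested
with a constant of 0.5 against the measured constant of about 0.2.

**An empirical finding.** The theory proves endemic stability for
$1 < R_0 < 3$ and expects it for all $R_0 > 1$. On the reference family
($\kappa_1 = \kappa_2 = 1$, $m = 0.5$, $a_m = 2$, $d = 1$) the scan
instead finds a conjugate root pair crossing the imaginary axis at
$R_0 = 4.90$ (scan step 0.05), at mode $\mu = 0$ and frequency
$\approx 0.94$ — a Hopf-type loss of stability of the spatially constant
dynamics, consistent with the Hopf bifurcations known for the
non-diffusive version of this model. The discrete linearization matrix
reproduces the crossing. Verdicts for $R_0 \ge 3$ are therefore labelled
"conjectural regime" in the report and are empirical, not asserted from
theory.

## Scenario generator

`make_scenario()` is the package's synthetic world. Defaults state the
reference conditions used throughout the analysis: $\kappa_1 = \kappa_2 =
1$, constant mortality $m = 0.5$, $a_m = 2$ (so an infected individual
survives the full infectious period with probability $e^{-1}$), unit
diffusion on the unit interval, no recovery, and a constant transmission
rate obtained by inverting $R_0 = \kappa_2 b \int_0^{a_m}\Pi$ — exact to
round-off because inversion and evaluation share one quadrature.
Initial data are a smooth 20% spatial modulation of carrying capacity
with a 10% infected seed proportional to $\Pi(a)$: smooth, strictly
positive, renewal-incompatible (deliberately — the simulator must digest
that). Heterogeneous (Dirichlet) scenarios add seeded, bounded,
positivity-preserving low-frequency perturbations of $b$ and support only
approximate $R_0$ targeting via the spectral radius, since no closed form
exists; requesting exact targeting there is an error, not a silent
approximation.

What a green test on this world does **not** establish: behavior under
rough or strongly heterogeneous coefficients, large domains with fine
spatial structure, $a_m$-truncation effects, or any quantitative claim
about real epidemiological data — no fitting facilities are provided.

## Numerical choices and tolerances (summary)

| Quantity | Choice | Default |
|---|---|---|
| Age quadrature | composite trapezoid, Richardson-checked | 2001 nodes, rtol $10^{-10}$ |
| Survival $\Pi$ | cumulative trapezoid of $m$, then `exp` | deterministic, no ODE solve |
| Diffusion solves | sparse Cholesky of $I - \Delta t\, d\, L_h$ | factorized once per age node |
| Newton (steady states) | Armijo damping, positivity floor | scaled residual $10^{-10}$ |
| Power iteration | all-ones start, Rayleigh tolerance | $10^{-10}$, cap $10^4$ iters |
| Spectral bound | bracketed bisection | $|s|$ tol $10^{-8}$ |
| Root residuals | Newton polish with analytic $H'$ | $10^{-12}$ (bound $10^{-9}$) |
| Stability verdicts | inconclusive band around 0 | $\pm 10^{-6}$ |

Degenerate inputs are errors, not warnings: misaligned $\Delta t$,
negative densities, Dirichlet mass-balance requests, recovery in the
logistic-bound check, $R_0 \le 1$ endemic constructions, $R_0 > 1$
collapse scans, and contour roots that defeat the winding computation
after refinement.

## Known limitations

* First-order accuracy in $\Delta t = \Delta a$ throughout; no adaptive
  stepping or higher-order age schemes.
* The Volterra renewal solver is first-order (left-rectangle first
  kernel node) and represents the uncoupled part of the linearized
  semigroup; it is a diagnostic and oracle, not a production propagator.
* Dense eigensolvers bound practical problem sizes to a few thousand
  unknowns per field.
* The endemic stability machinery requires spatially homogeneous Neumann
  data; heterogeneous endemic stability is only accessible through the
  discrete linearization matrix, without a mode-decomposition
  cross-check.
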