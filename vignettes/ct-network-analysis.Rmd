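---
title: "Continuous-time dynamical network analysis with ctdyn"
author: "ctdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous-time dynamical network analysis with ctdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdyn)
```

## The model

ctdyn analyses multivariate time series -- typically experience-sampling
(ESM) measurements of psychological states -- as *continuous-time dynamical
networks*. The generating model is the first-order linear stochastic
differential equation (the multivariate Ornstein--Uhlenbeck process)

$$\frac{dY(t)}{dt} = A\,\bigl(Y(t) - \mu\bigr) + W(t),$$

where the $p \times p$ *drift matrix* $A$ holds the moment-to-moment
effects: diagonal *auto-effects* (negative for mean-reverting processes;
more negative means faster return to equilibrium) and off-diagonal
*cross-effects* $a_{ji}$, the truly direct influence of variable $i$ on the
rate of change of variable $j$. $W(t)$ is a Wiener input with covariance
rate $Q$ (the `diffusion` of a `ct_model`), and $\mu$ is the equilibrium
(zero under the centered convention, which is the package default).

The integral form of this equation is the continuous-time VAR: observations
a time-interval $\Delta t$ apart satisfy

$$Y(t_\tau) = e^{A \Delta t_\tau}\, Y(t_{\tau-1}) + \epsilon(\Delta t_\tau),
\qquad \epsilon(\Delta t_\tau) \sim N\bigl(0, \Sigma(\Delta t_\tau)\bigr),$$

with $\Sigma(\Delta t) = \Gamma - e^{A\Delta t}\Gamma e^{A'\Delta t}$ and
$\Gamma$ the stationary covariance solving
$A\Gamma + \Gamma A' + Q = 0$. Because the transition holds for *any*
interval, irregular sampling -- randomized beeps, overnight gaps -- is
handled exactly, with no missing-data imputation or interval rounding.

The discrete-time VAR(1), $Y_\tau = c + \Phi Y_{\tau-1} + \epsilon_\tau$,
is the special case at one fixed interval: $\Phi(\Delta t) = e^{A\Delta t}$.
This mapping is the heart of the *time-interval problem*: lagged regression
parameters, and every network statistic computed from them, are functions
of the measurement interval. `lagged_params()`, `phi_curve()` and
`sign_switch_report()` make that dependence explicit; `dt_to_ct()` inverts
it where a real principal matrix logarithm exists.

A note on the body-text gap this package fills explicitly: the CT residual
covariance is often only described as "a function of the time-interval".
We adopt the standard Ornstein--Uhlenbeck discretization
$\Sigma(\Delta t) = \Gamma - e^{A\Delta t}\Gamma e^{A'\Delta t}$ and verify
it two independent ways in the test suite: against the scalar closed form
$q(1 - e^{2a\Delta t})/(-2a)$, and against the Monte-Carlo covariance of
50,000 exactly simulated transitions.

## Effects as interventions

Every effect in ctdyn is defined as an expected-value contrast under
do-interventions, which gives the measures their operational meaning:

* **Total effect** `total_effect(m, i, j, dt)`: a unit *pulse*
  $do(Y_i(t) = 1)$ versus leaving the system at equilibrium; equals
  $[e^{A\Delta t}]_{ji}$. Equivalently the $j$-th component of
  `pulse_trajectory()` -- an identity asserted across modules in the tests.
* **Direct effect** `direct_effect(m, i, j, M, dt)`: the same pulse with
  the mediator set $M$ *press-held* at equilibrium; equals
  $[e^{A^{(D)}\Delta t}]_{ji}$ where $A^{(D)}$ is the drift with every
  off-diagonal entry in the rows and columns of $M$ set to zero
  (`blocked_drift()`).
* **Indirect effect**: the difference, $IE = TE - DE$, computed literally
  as that difference so the additive decomposition is a floating-point
  identity. A *negative* indirect effect means the press *amplifies* the
  pulse's effect -- the signature of a blocked compensating (negative
  feedback) pathway.

**Blocking rule.** Worked examples in the literature sometimes zero only
the specific cause-to-mediator and mediator-to-effect entries that appear
in a lower-triangular example. We zero *both* the off-diagonal rows and
columns of $M$ (keeping the diagonal), because that is what "press the
mediators at equilibrium" does to an arbitrary drift matrix: inputs to the
mediators are irrelevant (their state is pinned) and their outputs
contribute nothing (their value is the equilibrium, zero). The two rules
coincide on the lower-triangular examples. The arbiter is semantic, not
typographic: `clamped_trajectory()` integrates the pressed system
directly, and the tests require the matrix-exponential direct effect to
match that trajectory to 1e-6 across random models -- plus an independent
fixed-step Runge--Kutta oracle outside the package code.

Because the model is linear, effects of pulses of any magnitude are the
unit-pulse effects scaled; `pulse_trajectory()` verifies linearity and
superposition directly.

## Centrality as intervention targeting

Two interval-resolved centrality measures summarize path-specific effects:

* **Total effect centrality** $TEC_i(\Delta t) = \sum_{j \ne i}
  TE_{ij}(\Delta t)$: the network-wide consequence of a pulse on $i$. It is
  identical to the one-step expected influence computed on
  $\Phi(\Delta t)$ -- the package asserts this equivalence to 1e-12 -- which
  reinterprets a familiar discrete-time measure as a *total*-effect summary.
* **Indirect effect centrality** $IEC_i(\Delta t) = \sum_{j \ne k;\, j,k \ne
  i} IE_{jk|i}(\Delta t)$: how much press-holding $i$ changes what the
  *other* variables do to each other. Positive: the press weakens
  transmission (a good press target). Negative: the press amplifies it
  (press elsewhere).

The classical discrete-time measures are provided for comparison on any
lagged matrix (`dt_centrality()`): one- and two-step expected influence,
out-strength, and betweenness. Two are under-specified in common usage and
we fix conventions explicitly:

* **EI2**: one-step direct effects plus lag-two total effects,
  $\sum_{j\ne i} \phi_{ji} + \sum_{j\ne i} [\Phi^2]_{ji}$. Near
  $\Delta t = 0$, where $\Phi \approx I + A\Delta t$, the lag-two sums
  duplicate the lag-one sums, so EI2 $\approx$ 2 EI1 -- checked numerically.
* **BC**: betweenness on the directed graph of absolute weights with edge
  length $1/|w|$, Dijkstra shortest paths, fractional counting of ties,
  self-loops ignored (the convention of standard network software,
  implemented via igraph). The tests cross-check it against exhaustive
  simple-path enumeration on all graphs up to five nodes.

Expected-influence measures keep their sign; out-strength and betweenness
use absolute weights.

## Interventions beyond effects

`press_trajectory()`, `press_equilibrium()` and `press_stability()` treat
the press intervention as a system operation: holding a set $S$ fixed
leaves the free variables with dynamics $A_{-S,-S}$ and a new equilibrium
$\mu_{-S} - A_{-S,-S}^{-1} A_{-S,S}(v - \mu_S)$. Pressing at the
equilibrium value displaces nothing. Importantly, a system that is stable
as a whole can have an *unstable* free subsystem -- pressing can
destabilize the rest of the network -- which `press_stability()` reports
via the eigenvalues of the principal submatrix. Finite-duration presses
release the full dynamics from the state at release; this is an extension
beyond the indefinite press and is off by default.

Trajectories here are *expected values* (the deterministic part of the
linear system); stochastic sample paths belong to the simulator.

## Estimation

`fit_ct_var()` maximizes the exact transition likelihood: conditioning on
the first observation, each consecutive fully observed pair contributes a
Gaussian term with mean $e^{A\Delta t_\tau} Y(t_{\tau-1})$ and covariance
$\Sigma(\Delta t_\tau)$. Design choices:

* **Centering.** Variables are mean-centered before fitting (the centered
  convention); the sample means are stored as the equilibrium of the
  returned model. We do not correct the standard errors for this
  pre-processing step.
* **Parameterization.** Drift entries are unconstrained ($p^2$ reals); the
  diffusion is parameterized by its lower-triangular Cholesky factor with
  logged diagonal, guaranteeing positive semi-definiteness without
  constrained optimization.
* **Stability handling.** Trial parameter points with an unstable drift or
  a degenerate transition covariance receive a large finite penalty rather
  than an error or a hard constraint; hard constraints would distort the
  Hessian-based standard errors at the optimum.
* **Warm start.** The first optimizer start converts the pooled-OLS
  discrete-time fit at the median interval back to continuous time through
  the matrix logarithm (when it exists); remaining starts are random
  perturbations (default 10 starts; the replication studies in the tests
  use 2, which the warm start makes sufficient for these problem sizes).
* **Missing data.** Any pair with a missing entry in either row is dropped
  (listwise by pair) -- the simplest correct conditional likelihood.
  Partial-row conditioning would be a possible extension.
* **Long gaps.** Overnight gaps are retained as-is: since
  $\Phi(\Delta t) \approx 0$ for large $\Delta t$, those transitions
  predict (approximately) the equilibrium and contribute almost nothing to
  the drift estimate, which is the statistically correct weighting.
* **Implementation.** The per-pair likelihood is evaluated in the
  eigenbasis of $A$ in compiled code, so a full likelihood at $n = 2000$
  pairs costs well under a millisecond; quasi-Newton optimization with
  numerical gradients is then entirely practical.

`fit_dt_var()` is the deliberately naive baseline: per-equation OLS
pooling all consecutive pairs regardless of interval. On unequal intervals
its lagged matrix is a blend of the lagged relationships at the intervals
present in the data -- the tests demonstrate this with a two-interval
design where the pooled estimate falls far from
$\Phi(\mathrm{median}\ \Delta t)$.

`propagate_uncertainty()` re-samples parameter vectors from
$N(\hat\theta, \widehat{\mathrm{vcov}})$ (the frequentist likelihood
approximation) and maps each draw through any functional of the model --
a lagged-parameter entry over a grid, a centrality curve, an effect curve
-- returning pointwise 2.5/97.5 percentile bands. Bands are seeded and
exactly reproducible; a non-PSD covariance (possible with a near-singular
numerical Hessian) is repaired to the nearest PSD matrix with a warning.

## The synthetic-data generator

`sample_ou_path()` simulates the process *exactly* on any schedule using
the transition distribution itself -- no Euler--Maruyama discretization --
so simulator error can never contaminate estimator tests. The first state
is a stationary draw (or a supplied initial state), and each subsequent
state is $N(e^{A\Delta t} y_{\mathrm{prev}}, \Sigma(\Delta t))$.

`esm_schedule()` emulates the randomized beep schedules of
experience-sampling protocols: the waking window (default 13.5 h) is split
into one block per beep (default 6/day) with one uniform draw per block,
days separated by the overnight gap. This reproduces the qualitative
structure of real ESM interval distributions -- right-skewed, a couple of
hours within days, an overnight mode -- though not every quantitative
detail: with these defaults the overall median interval is about 2.5 h,
somewhat above the ~2 h medians of comparable empirical protocols, because
the stratified blocks are more regular than real beep schedules. The
generator also does not emulate Likert discretization, floor effects, or
structured (non-random) missingness; passing tests therefore demonstrate
correctness of the estimator under the model, not robustness to those
real-data features.

`example_models()` provides three fixtures. The Stress--Discomfort system
anchors exactly four drift entries to published point values
($a_{11}=-6$, $a_{22}=-2.5$, $a_{42}=-7.3$, $a_{41}=0$); the full matrix
behind the published figures is not printed anywhere, so the remaining
entries are synthetic, chosen once to make the model stable and to
reproduce two qualitative phenomena -- a lagged effect that switches sign
over the interval (negative direct, positive indirect pathway) and a
single negative feedback loop through Physical Discomfort. Entry
provenance is recorded in the fixture's `provenance` attribute, and no
test asserts any published *output* value computed from the unpublished
entries.

## Numerical choices

* Matrix exponentials use Pad&eacute; scaling-and-squaring (the Matrix
  package). The interval-halving identity
  $\Phi(1) = \Phi(1/2)^2$ holds to 1e-10 across random stable models, and
  the latent-wave product limit $(I + A\Delta t/n)^n$ converges to it at
  rate $1/n$.
* The matrix logarithm (for `dt_to_ct()`) is the principal branch,
  computed by inverse scaling-and-squaring (repeated square roots, a
  truncated series, then Newton refinement against the exponential to
  ~1e-14). Lagged matrices with an eigenvalue on the closed negative real
  axis have no real logarithm (negative auto-regression) and raise an
  error; complex eigenvalues trigger an aliasing warning, since several
  drift matrices are then consistent with the same lagged matrix.
* Lyapunov equations (stationary covariance, discrete counterpart) are
  solved by Kronecker vectorization -- adequate and exact for the small
  $p$ this package targets (solve cost grows as $p^6$; tens of variables
  would need a Bartels--Stewart solver).
* Symmetry/PSD tolerances are 1e-8 relative, with PSD checks allowing
  eigenvalues down to -1e-10.
* Sign-switch detection scans the curve grid (default step 0.05 over 0--5
  time units, matching the interval range of interest for ESM data) and
  refines each bracket by bisection to width 1e-4; the curves are
  analytic, so adjacent-sign brackets on a reasonably fine grid find all
  crossings in practice (a tangential touch without crossing is invisible
  to any sign-based scan).
* Variable indexing is 1-based, the R convention; all user-facing
  functions accept labels as well as indices, and labels are the
  recommended interface.

## Problem sizes in the test suite

The replication studies in the tests use 4-variable systems with 2000
observations (334 simulated days at 6 beeps/day) against 500 observations
for the consistency comparison, 20 replications with 2 optimizer starts
each, 50,000 transitions for the Monte-Carlo covariance calibration, and
50-model sweeps for the exact identities. These sizes make every
statistical check decisive at its stated tolerance while keeping a full
run of the suite in the minutes range.

## Limitations

* Single-subject, stationary, linear dynamics only: no multilevel
  structure, time-varying parameters, measurement-error/latent-state
  layer, or nonlinear/multi-attractor models.
* Causal readings of fitted effects inherit all the usual assumptions --
  modularity, no unobserved confounding, correct model specification.
  Press-intervention effects are especially sensitive to the latter.
* The matrix-logarithm inversion is subject to aliasing: distinct drift
  matrices can imply the same lagged matrix at one interval. We surface
  this as a warning rather than attempting to resolve it.
* Fitting tens of variables is out of scope (parameter count grows as
  $p^2$ and the Kronecker Lyapunov solver as $p^6$).
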