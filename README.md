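# ctdyn: continuous-time dynamical network analysis

Dynamical network analyses of intensive longitudinal data (experience
sampling, ambulatory assessment, daily diaries) usually estimate a
discrete-time VAR(1) and read its lagged matrix as a network of direct
effects. That practice has a structural flaw: lagged regression parameters
depend on the time between measurements — `Φ(Δt) = e^{AΔt}` — so every
edge, every centrality value, and every intervention recommendation is
specific to one sampling interval, and irregular sampling makes the pooled
estimates a blend across intervals. ctdyn implements the continuous-time
alternative for researchers who want interval-honest answers:

* **Model.** The first-order stochastic differential equation
  `dY(t)/dt = A(Y(t) − μ) + W(t)` (the multivariate Ornstein–Uhlenbeck
  process), whose drift matrix `A` holds the moment-to-moment *direct*
  effects — the weighted local dependence graph.
* **Discretization.** Exact mappings in both directions: `lagged_params()`
  and `residual_cov()` give `Φ(Δt) = e^{AΔt}` and
  `Σ(Δt) = Γ − e^{AΔt} Γ e^{A'Δt}` at any interval; `dt_to_ct()` inverts
  via the principal matrix logarithm; `phi_curve()` and
  `sign_switch_report()` expose the interval dependence, including effects
  that change sign over Δt.
* **Path-specific effects as interventions.** `total_effect()` (a pulse
  `do(Y_i = 1)`), `direct_effect()` (the same pulse with mediators
  press-held at equilibrium, via a blocked drift matrix), and
  `indirect_effect()` (their difference), all as functions of Δt, each
  cross-checked against simulated intervention trajectories.
* **Centrality for choosing intervention targets.** Total Effect
  Centrality (best pulse target) and Indirect Effect Centrality (best
  press target) as interval-resolved curves, alongside the classical
  discrete-time measures (expected influence, out-strength, betweenness)
  computed on `Φ(Δt)` for comparison.
* **Interventions.** Expected trajectories under pulse and press
  do-operations, post-press equilibria, and stability of the pressed
  system (`press_stability()` — pressing a variable can destabilize the
  rest of the network).
* **Estimation.** Exact maximum likelihood for irregularly sampled data
  (`fit_ct_var()`, compiled likelihood kernel, multi-start quasi-Newton),
  the pooled-OLS DT-VAR baseline (`fit_dt_var()`), and likelihood
  re-sampling uncertainty bands for any derived curve
  (`propagate_uncertainty()`).
* **Simulation.** Exact stochastic simulation on arbitrary schedules
  (`sample_ou_path()`) and a randomized ESM beep-schedule generator
  (`esm_schedule()`), so the whole pipeline is testable end to end without
  any external dataset.

## Worked example

The built-in four-variable Stress–Discomfort system (four drift entries
anchored to published values, the rest synthetic and documented as such):

```r
library(ctdyn)
m <- example_models()$stress_discomfort_partial
m
#> Continuous-time VAR model (4 variables: Stress, Anxiety, SelfCon, Discomfort)
#> Drift matrix A:
#>            Stress Anxiety SelfCon Discomfort
#> Stress         -6     2.0       0          0
#> Anxiety         1    -2.5       0          1
#> SelfCon         0     2.0      -3          0
#> Discomfort      0    -7.3       3         -4
#> Stable: TRUE
```

The lagged network implied at a half-hour interval — note the strong
*negative* Anxiety → Discomfort edge, which the drift's direct effect
(−7.3) dominates at short intervals:

```r
round(lagged_params(m, 0.5), 3)
#>            Stress Anxiety SelfCon Discomfort
#> Stress      0.071   0.105   0.018      0.029
#> Anxiety     0.052   0.165   0.070      0.082
#> SelfCon     0.035   0.210   0.248      0.047
#> Discomfort -0.089  -0.455   0.192      0.013
```

At longer intervals the positive indirect pathway through
Self-Consciousness takes over and the same lagged effect changes sign —
the package locates the crossing:

```r
sw <- sign_switch_report(phi_curve(m, seq(0, 2, 0.02)))
sw[sw$from == "Anxiety" & sw$to == "Discomfort", c("from", "to", "dt")]
#>      from         to       dt
#> 2 Anxiety Discomfort 1.276836
```

Centrality as intervention targeting: when each variable's pulse has its
largest network-wide consequence, and who is a good (or bad) press target:

```r
centrality_curve(m, "TEC", seq(0, 2, by = 0.05))
#> TEC centrality (CT) on 41 intervals in [0, 2]
#> Peak |value| interval per node:
#>     Stress    Anxiety    SelfCon Discomfort
#>       0.15       0.20       0.30       0.35

ci <- centrality_curve(m, "IEC", seq(0, 2, by = 0.05))
round(ci$node_values[11, ], 4)   # IEC at dt = 0.5
#>     Stress    Anxiety    SelfCon Discomfort
#>    -0.0157    -0.0319     0.1457    -0.0395
```

Self-Consciousness has positive IEC (press-holding it dampens how the
other variables activate each other); Discomfort's IEC is negative — it
carries the only negative feedback loop, so pressing it would *amplify*
transmission. Press interventions can also be simulated directly:

```r
round(press_equilibrium(m, "Anxiety", -1), 4)
#>     Stress    Anxiety    SelfCon Discomfort
#>    -0.3333    -1.0000    -0.6667     1.3250
```

Fitting works on any irregularly sampled series; here, data simulated on a
randomized ESM schedule:

```r
times <- esm_schedule(n_days = 60, beeps_per_day = 6,
                      waking_window_hours = 13.5, seed = 1)
y <- sample_ou_path(ct_model(random_stable_drift(4, seed = 2)), times, seed = 3)
fit <- fit_ct_var(y, n_starts = 2, seed = 4)
band <- propagate_uncertainty(fit, function(mod) total_effect(mod, 1, 2, c(0.5, 1)),
                              n_draws = 1000, seed = 5)
```

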