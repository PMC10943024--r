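# metacomdyn

Simulation of multitrophic metacommunities on **dynamic landscapes** —
spatial networks of temporary habitat sites (think temporary-pond systems)
that activate and deactivate on stochastically jittered yearly schedules.
The package is for theoretical ecologists studying how **local stabilizing
factors** (self-limitation λ, food-web trophic coherence via a temperature
parameter T) and **regional ones** (dispersal ability a) shape the
sensitivity of diversity and biomass patterns to increasing **landscape
asynchrony** A.

## The model in brief

* **Landscape**: n_P sites on a square in n_C spatial modules (excess factor
  F controls tightness), connected by the Euclidean MST plus random edges up
  to n_E = 2·n_P, sampled with probability ∝ d⁻ˣ. One site is a permanently
  active *mainland* holding the full species pool.
* **Schedule**: site p is active once a year for w_p ~ U(0.2, 0.3) years,
  starting at k + z_{p,k} with z ~ U(−A, +A); overlapping windows merge.
* **Local communities**: generalized Lotka–Volterra,
  dx_i/dt = (r_i + Σ_j M_ij x_j) x_i, with M_ii = −λ, prey–predator pairs
  (−𝒳, 0.4𝒳), 𝒳 lognormal (mean 1, sd 0.25). Growth rates solve the LP
  *max y\** s.t. r + Mx = 0, x_i ≥ y\* ≥ 0, r ≤ 1 (basal), r ≤ −0.01
  (consumers); webs that are LP-infeasible or whose Jacobian diag(x\*)·M is
  not Lyapunov-stable are discarded and redrawn.
* **Dynamics**: a continuous-time Markov chain of dispersal events at rate
  a/d (zero below 0.1), prey-gated colonization, instantaneous equilibrium
  recomputation with secondary-extinction cascades below the 0.001 biomass
  threshold, simulated with the first-reaction method.
* **Metrics**: time-averaged (continuous power mean) α/γ persistence and
  γ/β biomass; 𝒫_β = 𝒫_γ/𝒫_α; asynchrony sensitivities
  𝒮[x] = (x_H − x_L)/(A_H − A_L) with A_L = 0, A_H = 0.5; standardized
  effect-size regressions on z-scored T, λ, â = log₁₀ a with all quadratic
  interactions and AICc all-subsets model selection.

See `vignettes/metacommunity-model.Rmd` for assumptions, parameter
semantics, and numerical conventions.

## Worked example

Generate an accepted regional community, a modular landscape, an
asynchronous schedule, and simulate six years:

```r
library(metacomdyn)
comm  <- generate_stable_regional_community(n_s = 30, n_b = 6, n_l = 139,
                                            temperature = 0.2, lam = 0.47,
                                            seed = 11)
L     <- generate_landscape(n_p = 25, f = 50, seed = 2)
sched <- sample_activation_schedule(L, A = 0.5, years = 6, seed = 3)
traj  <- simulate_run(L, sched, comm$web, comm$dyn, a = 3000, seed = 4,
                      distance_scale = 1000)
summarize_run(traj)
```

which prints

```
regional community: accepted after 1 tries
foodweb: 30 species (6 basal), 139 links, C = 0.1997
  temperature = 0.2, incoherence q = 0.0000, max trophic level = 4.00
  lam = 0.47, y* = 0.04249, biomass range [0.04249, 0.5149]
landscape: 25 sites, 50 edges, 5 module(s), mainland = site 17
metacommunity trajectory: 25 sites, 30 species, 6 year(s), a = 3000
  2006 state interval(s), 2823 event(s) (activate: 132, deactivate: 143,
  dispersal: 1704, extinction: 436, failed_invasion: 408)
responses: P_alpha = 0.2270, P_gamma = 0.6607, P_beta = 2.9110,
           B_gamma = 6.194, B_beta = 1.2668
```

Reading this: the accepted 30-species web is highly coherent (q ≈ 0 at
T = 0.2) and its LP equilibrium keeps every species above y\* ≈ 0.042. Over
six years with strong asynchrony (A = 0.5) and fast dispersal, active sites
hold on average 23% of the pool (`P_alpha`), 66% of the pool is present
somewhere (`P_gamma`), so the regional pool is spread over ≈ 2.9
compositionally distinct site-equivalents (`P_beta`); 436 secondary
extinctions and 408 failed invasions occurred along the way.

Sweeps over (T, λ, a) grids with paired asynchrony levels, and the
effect-size tables, run through `run_sweep()` / `sweep_effect_sizes()`; a
thin command-line front end with `generate-landscape`, `generate-web`,
`build-community`, `simulate`, `sweep` and `effects` subcommands is in
`inst/scripts/metacom-cli.R`.

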