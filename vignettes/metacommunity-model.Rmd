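---
title: "Multitrophic metacommunities on dynamic landscapes: the model behind metacomdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitrophic metacommunities on dynamic landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacomdyn)
```

## The scientific problem

Temporary habitats — temporary ponds are the canonical case — form landscapes
whose sites switch between *active* (habitable) and *inactive* states once a
year, with timing that is only loosely synchronized across sites. Multispecies
communities living on such landscapes are shaped by two kinds of stabilizing
factors: *local* ones (self-limitation strength, trophic coherence of the food
web) that decide whether a community of interacting species can hold itself
together, and *regional* ones (dispersal among sites) that decide how fast
emptied sites are recolonized. `metacomdyn` implements a stochastic
metacommunity model built to ask how sensitive diversity and biomass patterns
are to increasing *asynchrony* in the sites' active periods, and how local and
regional factors shape that sensitivity.

The model has four layers, mirrored by the package's modules:

1. **Landscape** — a spatial network of sites with a permanently active
   *mainland* holding the full species pool.
2. **Activation schedule** — per-site yearly activity windows with a
   controllable asynchrony magnitude $A$.
3. **Local communities** — generalized Lotka–Volterra (GLV) food webs whose
   growth rates are parameterized by linear programming and screened for
   Lyapunov stability, and which are assumed to reach equilibrium
   instantaneously.
4. **Metacommunity dynamics** — a continuous-time Markov chain of dispersal
   events coupled to the schedule, simulated event-by-event with the
   first-reaction method.

## Landscapes and schedules

`generate_landscape(n_p, n_e, n_c, f, x)` lays `n_p` sites on the unit
square in `n_c` spatial modules, connects them by the Euclidean minimum
spanning tree, and adds random edges up to `n_e` (default $2 n_P$) with
probability $\propto d^{-x}$, so larger `x` favours short edges. Edge weights
are Euclidean distances.

*Module placement.* Module centers are uniform on the square; a site with
uniform draw $u$ and center $c$ is placed at $c + (u - c)/f$. We chose this
shrink-toward-center rule over a disc-of-radius-$R/f$ rule because it makes
the excess factor's two advertised limits exact: at $f = 1$ positions are
*exactly* uniform on the square (no discernible clustering, testable by
Kolmogorov–Smirnov), while large $f$ produces tight modules of linear extent
$\sim 1/f$, with no boundary clipping.

`sample_activation_schedule(L, A, years)` draws one nominal window length per
site, $w_p \sim U(0.2, 0.3)$ years, and starts the year-$k$ window at
$k + z_{p,k}$ with $z_{p,k} \sim U(-A, +A)$; the window ends $w_p$ later.
Negative starts are clipped to 0, overlapping windows are merged, and
intervals are **closed**: a site is active at both its activation and its
deactivation instant (the simulator fires (de)activation events exactly at
these times, deactivations first on ties). $A = 0$ means perfect synchrony;
$A = 0.5$ spreads starts over a whole year. The mainland is always active.

## Local communities

A regional pool is a food web of `n_s` species, the first
`n_b = round(0.2 n_s)` basal, with `n_l` prey-to-predator links and
*temperature* `T` controlling trophic coherence. Construction follows a
generalized preferential-preying scheme: each consumer takes a first prey
uniformly among species ordered before it (fixing a provisional trophic
level), and the remaining links are drawn without replacement with weight
$\exp(-(g - 1)^2 / 2\max(T, 10^{-6})^2)$ on the provisional level gap $g$. At
$T = 0$ every link spans exactly one level; large $T$ admits omnivory.
Coherence is measured on the *final* adjacency by the incoherence
$q$ = standard deviation of the prey-averaged trophic-level gaps over links
(population convention by default; `sample = TRUE` switches). Connectance is
$C = n_L / (n_S (n_S - n_B - 1) + n_B)$.

Per link, an interaction strength $\mathcal{X}$ is drawn from a lognormal
with mean 1 and standard deviation 0.25 — read as moments of the variate
itself ($\sigma_0^2 = \ln(1 + 0.25^2)$, $\mu_0 = -\sigma_0^2/2$;
`moments = "log"` switches to meanlog/sdlog 1/0.25). The community matrix has
$M_{ii} = -\lambda$ (self-limitation, $\lambda > 0$; the experiment grid uses
diagonals between $-1$ and $-1/3$), $M_{ij} = -\mathcal{X}$ for prey $i$ of
predator $j$, and $M_{ji} = 0.4\mathcal{X}$ (a fixed conversion efficiency).

Growth rates come from the linear program
$$\max y^* \quad \text{s.t.} \quad r + Mx = 0,\; x_i \ge y^* \ge 0,\;
r_i \le \rho \,(\text{basal}),\; r_i \le -\mu \,(\text{consumers}),$$
with $\rho = 1$ and $\mu = 0.01$: the most even feasible equilibrium the web
admits. Substituting $r = -Mx$ reduces it to an LP in $(x, y^*)$ with
nonnegative variables, solved by the simplex method (`boot::simplex`,
tolerance $10^{-10}$); $r$ is recovered as $-Mx^*$, so the equilibrium
identity holds to round-off by construction. Infeasible webs are discarded
and regenerated, as are webs whose GLV Jacobian
$J = \mathrm{diag}(x^*)\,M$ has any eigenvalue with nonnegative real part
(`generate_stable_regional_community` loops until both screens pass).

`local_equilibrium` computes the community a species subset settles into at
one site: structurally prune consumers with no prey in the set, solve the
linear subsystem, remove everything below the extinction threshold 0.001
(including negative solutions), and repeat until nothing is removed.
Removal is simultaneous per iteration — deterministic, order-independent, and
terminating within `length(present)` iterations. A singular subsystem
(non-generic with $\lambda > 0$) is resolved by declaring the most recent
invader extinct.

## Metacommunity dynamics

The state couples discrete presence/absence per site with continuous
equilibrium biomasses. A dispersal event of species $s$ from $p$ to $q$
requires both sites active, $s$ present in $p$ and absent from $q$, and $s$
basal or with at least one prey already in $q$ (prey-gated colonization).
Its rate is $a/d(p,q)$, floored to zero below 0.1. Arrivals trigger an
equilibrium recomputation at $q$ with cascades; the source is unchanged;
deactivation zeroes a site; activation opens an empty site. The next event
is drawn with the first-reaction method: independent exponential waiting
times per candidate, racing against the next scheduled (de)activation and
the horizon. Waiting times are redrawn after every event — statistically
exact by memorylessness, and robust to the candidate set changing.

Two implementation choices matter for efficiency and are exact for the
state trajectory:

* **Failed-invasion memoisation.** An arrival that is cascade-removed without
  changing the destination leaves the state exactly as before, so the same
  event would re-fire at rates up to $10^4$–$10^5$/year while never doing
  anything. Such events are logged once and suppressed until the
  destination's composition changes.
* **Distance scale.** Coordinates live on the unit square; `simulate_run`
  takes a `distance_scale` (default 1) interpreted as the square's physical
  side length in the units of `a`. With raw unit-square distances a
  dispersal-ability range like $[30, 3000]$ is saturating everywhere and the
  0.1 cutoff can never trigger; the experiment-level default
  (`sweep_config(distance_scale = 1000)`) makes $a = 30$ dispersal-limited
  and $a = 3000$ fast, which is the regime in which the dispersal gradient
  is informative.

A run starts at $t = 0$ with the mainland full and every other site empty
(active if its window covers 0; the model is silent on pre-season occupancy,
so newly active sites always start empty and fill by dispersal). The output
trajectory stores piecewise-constant per-site richness/biomass summaries
between events plus a full event log.

## Response metrics and the asynchrony experiment

Instantaneous *alpha* persistence is mean site richness over the **active
non-mainland** sites divided by `n_s`; *gamma* is the non-mainland species
union over `n_s`. Gamma biomass is summed non-mainland biomass; beta biomass
is the coefficient of variation (population SD/mean) of site totals across
active non-mainland sites. The mainland is excluded throughout — including
it would pin $\mathcal{P}_\gamma \equiv 1$. Time averaging uses the
continuous power mean $\left(\frac{1}{W}\int f^p\right)^{1/p}$ with $p = 1$
by default ($p = 0$ is handled as the geometric-mean limit); intervals where
a metric is undefined (no active site for alpha; fewer than two for the CV)
are excluded from the measure rather than counted as zero
(`count_empty_as_zero` flips this). Beta persistence is the ratio of the
averaged scalars, $\mathcal{P}_\beta = \mathcal{P}_\gamma /
\mathcal{P}_\alpha$, undefined when $\mathcal{P}_\alpha = 0$.

The asynchrony sensitivity of a response $x$ is
$\mathcal{S}[x] = (x_H - x_L)/(A_H - A_L)$ with referential levels $A_L = 0$,
$A_H = 0.5$. `run_sweep` pairs the two runs of a replicate — same community,
landscape and window lengths $w_p$, different jitters and event noise — a
variance-reduction choice; the replicate's community and landscape are also
shared across the dispersal grid so contrasts in `a` are paired.

Effect sizes are coefficients of an ordinary least-squares fit of
$\mathcal{S}[x]$ on the z-scored mains $T$, $\lambda$, $\hat{a} =
\log_{10} a$ plus their three pairwise products and three squares (products
and squares formed after standardization). All $2^9$ models nested in the
full one (intercept always included, no hierarchy constraint) are ranked by
$\mathrm{AICc} = n\ln(\mathrm{RSS}/n) + 2k + 2k(k+1)/(n - k - 1)$. The RSS
is floored at $n \max(\overline{y^2}, 1)\,\varepsilon^{3/2}$ (machine
epsilon $\varepsilon$) so that exactly-fitting candidates are ranked by
parsimony instead of by the logarithm of floating-point dust. Note that a
grid with only two levels of a main predictor makes its squared z-score
constant; the full quadratic model needs at least three levels per main.

## The single-site assembly experiment

The limiting case of local stability is one permanently available site with
unlimited access to the pool. `assemble_community` lets absent species
invade one at a time in random order (prey-gated, cascades recomputed per
arrival, invaders that failed under the current residents not retried until
the residents change) until no absent species can establish. Although every
accepted pool coexists stably *as a whole*, the one-at-a-time path can
terminate in an invasion-resistant sub-community; this — not threshold
crossings of the full-pool equilibrium, which the max–min LP makes
essentially impossible — is what depresses persistence for unstable-prone
pools (high $T$, weak self-limitation). The walk is capped at
`50 * n_s` attempts, which in practice is reached only deep in the
unstable-prone corner where invasion/extinction churn continues
indefinitely.

## What the generators emulate, and what they do not

All inputs are synthetic by design: the model world is the object of study.
The landscape generator emulates modular pondscapes (clustered sites,
distance-dependent connectivity) but no real geography: no barriers,
site-quality differences, rasters or 3-D structure. Schedules emulate
quasiperiodic wet seasons with jitter, not multi-year droughts or
within-season rewiring. Food webs have controlled coherence but no niche- or
cascade-model structure, no cannibalism and no cycles; all species share one
dispersal ability; there are no dormant stages. Passing tests therefore
certify the model's internal contracts and reported qualitative behaviors,
not predictions for any particular empirical system.

## Numerical conventions, in one place

* LP feasibility/optimality tolerance $10^{-10}$; $y^*$ within tolerance of
  0 accepted; equilibrium residual $\|r + Mx^*\|_\infty$ exact to round-off.
* Stability is a strict eigenvalue test, $\max \mathrm{Re} < 0$.
* Extinction threshold 0.001 biomass units, applied to every recomputed
  equilibrium, simultaneous removal per cascade iteration.
* Closed activity intervals; event-tie order: deactivate < activate <
  dispersal, then site index.
* One root seed per user-facing generator, with independent child seeds per
  construction phase; `run_sweep` derives all replicate seeds from
  `config$seed`, so results tables reproduce bit-for-bit.
* Incoherence and biomass-CV use population standard deviations by default;
  both expose the sample convention.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen to finish in minutes while
leaving the tested contrasts unambiguous: webs of 10–30 species (the
coherence and stability checks use $n_S = 30$, $C = 0.2$, the smallest
richness of the reference experiment grid), landscapes of 6–50 sites,
6 simulated years, and 15–20 replicates per contrast. The assembly-gradient
check runs at $n_S = 30$ because at substantially smaller richness the
entire $(T, \lambda)$ plane is stability-prone and the gradient vanishes —
consistent with the observation that richness shrinks the high-persistence
region. Full-scale sweeps (hundreds of grid cells, 50 replicates, webs up to
75 species, 100 sites) use the same code paths through `run_sweep`; they are
a cluster-scale undertaking and deliberately not part of the tests.

## Known limitations

* Equilibria are recomputed instantaneously; systems with long local
  transients may behave differently (a scope choice inherited from the
  model's separation of time scales).
* `boot::simplex` is a dense simplex implementation; webs beyond a few
  hundred species would want a sparse LP solver.
* The event loop is exact but serial; very fast dispersal with many blocked
  invaders relies on the memoisation above for tractability.
* `P_beta` is undefined for runs in which no non-mainland site is ever
  colonized (`P_alpha = 0`), and such replicates drop out of
  sensitivity averages.
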