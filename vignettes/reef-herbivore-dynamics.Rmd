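---
title: "Herbivore functional groups and coral reef bistability: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Herbivore functional groups and coral reef bistability: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`reefherb` simulates a coral reef benthos in which coral ($C$), turf
algae ($T$) and macroalgae ($M$) compete for space, coupled to three
herbivorous fish functional groups: grazers ($G$, strict turf
specialists), browsers ($B$, strict macroalgal specialists) and
generalists ($R$, consuming turf and macroalgae in proportion to their
abundance). All benthic variables are proportions of space; the
remainder $S = 1 - C - T - M$ is unoccupied.

Each benthic group colonises unoccupied space by propagule import
($i_C, i_T, i_M$) and lateral expansion of existing cover
($b_C, b_T, b_M$):

$$\frac{dC}{dt} = (i_C + b_C C)\,S\,\bigl(1 - (\alpha_T T + \alpha_M M)\bigr) - d_C C$$

$$\frac{dT}{dt} = (i_T + b_T T)\,S - \gamma T
  - \frac{g_T T G}{g_T \eta_T T + 1}
  - \frac{g_T T R}{g_T \eta_T T + g_M \eta_M M + 1}$$

$$\frac{dM}{dt} = (i_M + b_M M)\,S + \gamma T
  - \frac{g_M M B}{g_M \eta_M M + 1}
  - \frac{g_M M R}{g_T \eta_T T + g_M \eta_M M + 1}$$

$$\frac{dX}{dt} = r X \Bigl(1 - \frac{G + B + R}{(1-\sigma) + \sigma C}\Bigr) - f X,
  \qquad X \in \{G, B, R\}$$

Coral recruitment and growth are depressed by algal competition
($\alpha_T, \alpha_M$, with $\alpha_M > \alpha_T$: macroalgae compete
harder); uncropped turf matures into macroalgae at rate $\gamma$.
Herbivory saturates with algal cover (Holling type II with handling
times $\eta_T, \eta_M$); the generalist terms share one denominator
across both algae, which is what makes generalist consumption
proportional to availability. The three destabilising positive
feedbacks are: herbivory rates that rise with algal cover, algal
suppression of coral recruitment, and a herbivore carrying capacity
$K(C) = (1-\sigma) + \sigma C$ that grows with coral cover (shelter
provision). Fishing is a constant per-capita mortality $f$ applied
equally to all groups.

Because the three herbivore groups share identical per-capita dynamics,
their ratios are frozen at the initial composition and the total
$H = G + B + R$ obeys a single logistic with equilibrium
$H^* = K(C)\,(1 - f/r)$ at fixed coral cover — both properties are
asserted in the test suite, and the second is used as a convergence
check on every steady state.

## Parameters

Defaults of `reef_params()` (rates per year unless dimensionless):

| symbol | default | meaning |
|---|---|---|
| `i_C`, `i_T`, `i_M` | 0.05, 0.05, 0 | propagule import; macroalgae recruit only from turf |
| `b_C`, `b_T`, `b_M` | 0.3, 0.8, 0.5 | expansion of existing cover; turf fastest |
| `d_C` | 0.1 | background coral mortality |
| `gamma` | 0.1 | turf-to-macroalgae maturation |
| `g_T`, `g_M` | 2, 1 | maximal herbivory; turf is consumed faster |
| `eta_T`, `eta_M` | 0, 1 | handling times; turf needs no handling |
| `alpha_T`, `alpha_M` | 0.25, 0.5 | algal competition on coral |
| `r` | 1 | herbivore intrinsic growth |
| `sigma` | 0.6 | weight of coral in carrying capacity |
| `f` | 0 | fishing pressure (varied by every analysis) |

Parameter sets serialise to flat YAML/JSON keyed by these names
(`read_params()` / `write_params()`); unknown keys are an error so that
typos in a config cannot silently fall back to defaults.

## The scenario generators

All inputs to the analyses are generated, full-factorial initial
condition grids; there is no sampling anywhere, so every result is
exactly reproducible. Axis values are computed as integer multiples of
the step, never by repeated addition, so grids are identical across
platforms.

* `q1_grid()`: the aftermath of a major disturbance — coral 0.15, turf
  0.7, no macroalgae — with grazer and browser abundances on a 0.025
  lattice (total herbivores at most 0.9) for generalist levels 0, 0.2,
  0.4, crossed with fishing pressures.
* `q2_grid()`: coral fixed at 0.15 while initial turf and macroalgae
  vary from 0 to 0.7 (total benthic cover at most 0.85) for a fixed
  dominance community. The algal axes use the same 0.025 lattice
  density as the Question-1 grids; no finer step is needed because the
  outcome boundaries in this plane are single sharp fronts.
* `q3_grid()`: initial coral cover 0 to 0.85 crossed with fishing 0 to
  1, both in 0.01 steps (8686 scenarios); after reserving a 0.15 empty
  allowance the leftover benthos is split evenly between turf and
  macroalgae.

Herbivore initial values in these tables are proportions of the shared
carrying capacity: `run_scenarios()` multiplies them by $K(C_0)$ before
integrating (a community of "0.9" always starts at 90% of its
capacity, whatever the initial coral cover). This keeps every seeded
community below its capacity, which an absolute reading cannot do once
$K(C_0) < 0.9$, and it is the convention under which the analyses'
reported thresholds are calibrated. `herbivore_scale = "absolute"`
switches to literal abundances; with the default parameters the choice
moves basin boundaries by one to two grid cells (for example the
grazer-dominated zero-fishing recovery threshold shifts from 0.27 to
0.25) and leaves all qualitative conclusions unchanged.

Dominance presets give the dominant group 0.6 of the 0.9 total and
0.15 to each minor group; `dominance_community()` generalises this to
arbitrary fractions with the remainder split equally.

## Numerical choices

* Integration uses `deSolve::lsoda` with the right-hand side compiled
  in C, relative tolerance $10^{-8}$ and absolute tolerance $10^{-10}$.
  Tight tolerances matter because trajectories shadow invariant
  manifolds (herbivore abundances of order $10^{-6}$ and below during
  reverse hysteresis sweeps); loose error control there corrupts
  whether a population can re-expand when fishing is relaxed.
* "Steady state" is operational: the state at $t = 1000$ years, with
  the max-norm of the derivatives reported as `rhs_norm` and checked
  against $10^{-5}$. Away from basin boundaries the residual is
  typically below $10^{-10}$; scenarios within a grid cell of a
  boundary may converge more slowly and are reported with a warning,
  never silently dropped. Doubling the horizon changes converged final
  coral covers by less than $10^{-4}$.
* Components may undershoot zero by the integrator's error tolerance;
  the compiled right-hand side evaluates with negatives clipped at
  zero, and final states are clipped if above $-10^{-6}$ and rejected
  as corrupt otherwise. No extinction floor is applied: herbivores may
  become arbitrarily small but positive, which is essential for the
  reverse hysteresis sweeps.
* Exact zeros are absorbing: a group seeded at zero stays identically
  zero, so the turf-only submodel ($M_0 = B_0 = 0$, $i_M = 0$,
  $\gamma = 0$) is an exact invariant manifold. On it the model
  collapses to a three-variable single-algae, single-herbivore system
  (`reduced_derivatives()`), which the tests integrate independently
  and compare against the full model — an end-to-end oracle for both
  the equations and the integrator.
* Outcome classification: final coral above 0.6 is the high-coral
  state, below 0.2 the degraded state. The dominant alga is whichever
  of turf/macroalgae has the larger final cover; both below 0.01 counts
  as none, and exact ties go to macroalgae. The 0.01 floor and the tie
  rule are this package's conventions; outcomes are insensitive to
  them because final covers cluster far from the boundaries.

## Bistability and hysteresis

`bistability_map()` classifies every `q3_grid()` scenario; a fishing
pressure is *bistable* when its column contains both high- and
low-coral outcomes depending only on initial coral cover, and
`recovery_threshold()` reports the smallest initial coral cover that
reaches the high state (at grid resolution — the smallest recovering
grid value, matching how such thresholds are quoted at 0.01
resolution).

`hysteresis_sweep()` ratchets fishing from 0 to 1 and back in 0.005
steps, warm-starting each 1000-year run from the previous final state.
The forward sweep is seeded with the equilibrated, fishing-free state
of a coral-dominated reef ($C_0 = 0.7$, leftover benthos split evenly
between the algae, herbivores per preset); the reverse sweep continues
from the forward end point at $f = 1$. The seeding is a package
convention (any seed on the coral-dominated branch gives the same
curves, because the warm-started sweep immediately locks onto the
branch); it is configurable via `seed_C0`.

Two readouts of hysteresis are provided. `hysteresis_width()` reports
where the branches separate by more than 0.05 in final coral cover —
the natural visual criterion for plotted forward/reverse curves.
`hysteresis_fishing_range()` instead requires the branches to occupy
opposite outcome states (one above 0.6, the other below 0.2), the same
definitions used for bistability. The distinction matters in one
regime: a fold whose upper branch lies below the high-coral threshold
(as happens for browser-dominated communities near the transition)
registers as a narrow separation but as neither bistability hallmark.
The internal-consistency property — hysteresis present if and only if
the bistable fishing range is non-empty, preset by preset — therefore
holds at the outcome-matched reading, and that is how the test suite
checks it.

`dominance_bistability_loss()` scans increasing dominance of one group
(default browsers, 0.60–0.80 in 0.05 steps; the scan grid is a
configurable convention) and reports the smallest fraction whose
bistable fishing range is empty. With the default parameters the
browser-dominated fold's upper branch sits just below the 0.6 outcome
threshold throughout the scan, so the outcome-based bistable range is
already empty at 0.60 even though the narrow fold itself (visible to
`hysteresis_width()`) persists to higher fractions — see the README's
reproduction notes for how this is reported.

## Problem sizes

The packaged analyses integrate: 4107 scenarios for the Question-1
composition grids (three generalist levels, three fishing levels),
about 1300 per community for Question 2, 8686 per community for the
full-resolution bistability maps, 1890 for the browser-dominance scan
at its coarsened 0.05 grid, and 402 warm-started runs per hysteresis
pair. A single 1000-year integration takes well under a millisecond
with the compiled right-hand side, so each analysis completes in
seconds on one core.

## What the generated scenarios do and do not represent

The grids emulate idealised post-disturbance states: a storm or
bleaching event instantaneously sets benthic covers and the herbivore
community, after which the deterministic dynamics play out under
constant fishing. Passing tests therefore demonstrate properties of
the model — basin structure, threshold positions, path dependence —
not of any empirical reef. Real reefs experience stochastic
recruitment, spatially patchy disturbance, herbivore behaviour and
life-history differences among species within a functional group, and
fishing that is selective rather than uniform; none of these are
represented. The herbivore groups share one growth rate, one fishing
mortality and one shelter dependence, so community composition changes
only through initial conditions — relative abundances are conserved
along every trajectory. These simplifications are the point (they
isolate the pure effect of the grazing/browsing/generalist split), but
they mean quantitative thresholds such as the 0.27 recovery boundary
are illustrative of the mechanism, not predictions for a particular
reef.
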