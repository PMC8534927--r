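---
title: "Modelling variable-step motor traffic with dynlane"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling variable-step motor traffic with dynlane}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynlane)
```

## The model

`dynlane` simulates a driven lattice gas of hard-core particles that mimics
collective dynein traffic on a microtubule.  The track is a cylinder of
`Ly` lanes (protofilaments) with periodic transverse boundaries and `Lx`
columns with open longitudinal ends: particles are injected at the first
column of each lane with probability `alpha` per lane per Monte Carlo step
(MCS) and removed at the last column with probability `beta` per exit
opportunity.

What distinguishes a dynein-like walker from a plain TASEP particle is its
internal state.  Each motor carries four ATP binding sites: a primary
(hydrolysis) site that fuels movement, and three secondary sites that
represent load.  Per sweep, every site undergoes exactly one
attachment/detachment trial (`Patt`/`Pdet` for the primary site,
`Satt`/`Sdet` per secondary site).  A motor whose primary site holds ATP
attempts a jump of `4 - s` sites, where `s` is the number of loaded
secondary sites; a motor with an empty primary site does not move.  The
direction of each attempt is forward with probability `Px` and up or down
with probability `Py` each (`Px + 2 Py = 1`).  Jumps obey hard-core
exclusion with a *sliding* rule -- a blocked multi-step jump truncates to
the last empty site before the obstacle, so particles never overtake
within a lane -- and a realized hop of any length hydrolyses (empties) the
primary site, while a fully blocked attempt retains it.  A forward attempt
whose assigned length reaches or passes the last column triggers the
`beta` exit trial directly (mid-jump exit); if the trial fails the motor
is parked at the last column.

The study conditions fix `Patt = 0.8`, `Pdet = 0.2`, `Sdet = 1 - Satt`,
and three load levels: `Satt = 0.8` (high load, mostly unit steps), `0.5`
(intermediate) and `0.2` (low load, mostly 4-step jumps).  The
quasi-two-dimensional geometry uses `Py = 0.025` (`Px = 0.95`), matching
the observation that sidewise motion is much rarer than forward stepping.
These defaults are built into `kinetics_params()`.

### Secondary-site kinetics

The three secondary sites are modelled as independent two-state chains --
each site attaches with `Satt` when empty and detaches with `Sdet` when
occupied, once per sweep.  The stationary load is therefore Binomial(3,
`Satt/(Satt+Sdet)`) (`secondary_stationary_dist()`), and at the study
kinetics (`Satt + Sdet = 1`) the load re-equilibrates within a single
sweep.  An alternative reading of the kinetics -- one ATP arriving at one
available site per sweep, a birth-death chain on `s` with a truncated
geometric stationary law -- was considered and rejected: the independent
per-site trials follow the stated per-site probabilities directly, give
the cleaner product-form rates below, and fit the printed maximal-current
densities at least as well (binomial 0.442/0.352 versus birth-death
0.465/0.341 against 0.45/0.34).  One observable consequence is discussed
under *Known limitations*.

### Unobstructed jump rates

The per-MCS probability that a free motor hops `i` sites is the product of
the stationary primary occupancy and the load law,

```
R_i = Patt/(Patt + Pdet) * P(s = 4 - i),    s ~ Binomial(3, Satt/(Satt+Sdet)).
```

`jump_rates(params)` evaluates this (the normative `"binomial"` mode) and
a `"series"` cross-check mode that carries alternative `(1 - Pdet)`-style
prefactors for `R1`, `R2`, `R4`; the series form for `R3` does not exist
in a self-consistent closed form, so that entry always uses the binomial
expression.  The binomial mode is validated in the test suite against the
realized jump-length frequencies of a single unobstructed motor simulated
by the engine itself.  (At the study kinetics the two prefactor
conventions coincide numerically because `Patt + Pdet = 1`.)

## Update schedule

The engine uses uniformized random-sequential updating: one MCS consists
of `N + Ly` elementary draws *with replacement* over the current agents --
the `N` resident particles plus one entrance slot per lane.  Each agent is
visited once per MCS on average, so all rates are per-MCS probabilities,
and the chain is the discrete skeleton of the continuous-time process.

This choice was made after measurement, not by default.  A
permutation sweep (every particle exactly once per MCS, random order) was
implemented first and rejected: holes can relay through a cluster within
a single sweep whenever the order happens to run front-to-back, which
inflates the stationary current far beyond the continuous-time value (in
the unit-step limit at `alpha = beta = 0.9`, `r = 0.8` it gave bulk
density 0.556 and current 0.303 against the exact 0.5 and `r/4 = 0.2`).
Under the random-sequential schedule the unit-step limit reproduces the
open-TASEP phases to within sampling error, which is the calibration the
rest of the package stands on.

Because several elementary moves can fall within one MCS, event times are
recorded fractionally (sweep index plus draw position).  Dwell times are
reported as `ceiling()` of the elapsed time: they live on 1, 2, 3, ...
MCS, and an exponential waiting process of rate `lambda` maps exactly
onto a geometric law with `p = 1 - exp(-lambda)`, which is what
`fit_dwell()` exploits.

Entrants carry empty binding sites by default (`entry_state = "empty"`).
For unit-step (TASEP-limit) calibrations the package uses
`entry_state = "stationary"`, because an ATP-empty entrant in the
`Satt = 1` limit would perform a single 4-step jump before its
secondaries load, polluting the unit-step correspondence.

## Mean-field analysis

With factorized occupancies, the probability that a motor advances
exactly `i` sites combines bare rates with truncated longer jumps,

```
v4 = R4,  v3 = R4*rho + R3,  v2 = (R4+R3)*rho + R2,  v1 = (R4+R3+R2)*rho + R1,
```

and the bulk current is `J(rho) = rho * sum_i i * v_i * (1 - rho)^i`
(`mf_current()`).  Its maximizer `rho_max` (`mf_rho_max()`; coarse grid
plus bounded golden-section refinement, tolerance `1e-6`, deterministic)
is the bulk density of the maximal-current phase: 0.442 under high load,
0.352 under low load, 1/2 in the unit-step limit.  The MC phase opens at

```
beta  > 1 - rho_max,
alpha > rho_max * sum_i i * v_i(rho_max) * (1 - rho_max)^(i-1),
```

i.e. the injection rate whose entry-limited density reaches `rho_max`
(`mc_thresholds()`).  A variant of the alpha threshold with an extra
factor 2 was considered and rejected because it fails the unit-step
reduction `(r/2, 1/2)` that anchors the whole phase map; the form above
reduces exactly.  The `v_i` inside the threshold are evaluated at
`rho_max`, the density at which the boundary and bulk currents match.

## Observables and fits

* **Density profiles** (`measure_density()`): per-column time averages;
  the bulk estimate is the mean over the middle 50% of columns, with a
  standard error from 10 equal sampling blocks.
* **Currents** (`measure_current()`): bond-resolved crossings (a
  displacement of length `d` crosses `d` bonds, exits cross the exit
  bond), plus the net transverse current, which must vanish by up/down
  symmetry.  The identity `sum(bond crossings) = sum_d d * count_d` holds
  exactly per seed and is asserted in the tests.
* **Jump histograms** (`jump_histogram()`): realized post-sliding
  displacements 1-4 by axis.
* **Tagged particles** (`tag_particles()`): class A is the first entrant;
  classes B and C are the first entrants after `Lx` and `Lx^2` MCS,
  probing progressively crowded conditions.
* **MSD** (`msd_ensemble()`, `fit_msd()`): ensemble average over
  independent realizations, clocked from each particle's entry.  The
  default curve is the displacement *variance* (drift subtracted), the
  convention under which tagged-particle exclusion dynamics is compared
  with KPZ scaling; `detrend = FALSE` gives the raw second moment.  Fits
  of `A t^xi` or the log-corrected `A t^xi / ln t` are least squares on
  log axes and require a window of at least 1.5 decades and 100
  realizations.
* **Dwell times** (`dwell_times()`, `fit_dwell()`): waiting between
  consecutive realized jumps of the same particle, in whole MCS.  The
  single model is geometric; the double model is the two-stage
  convolution `P(W=k) = p1 p2 (q2^k - q1^k)/(q2 - q1)`, the discrete
  difference-of-exponentials shape produced by waiting for fuel *and*
  space.  A two-component mixture was deliberately not used: mixtures
  decay *slower* in the tail, whereas congested dwell histograms decay
  slowly at short times and cross over to a faster single rate, which is
  exactly the two-stage shape.  Model choice is by BIC; rates are
  reported as continuous-time equivalents `-log(1 - p)`.
* **Profile shapes** (`fit_profile()`): the maximal-current tangent form
  `rho_max (1 - q tan(q (x - x0)))` and the coexistence domain-wall
  `tanh`.  The tangent fit profiles `x0` over a deterministic grid
  because a flat profile makes the joint `(rmax, x0)` problem singular at
  `q -> 0`; `q` is bounded by `0.99 pi / span` so the tangent stays on
  one branch.
* **Oscillations** (`oscillation_period()`): dominant spatial
  autocorrelation lag of `rho(x) - rho_bulk` over the entrance region.

## Phase classification

The stationary phases are *defined* by the (in)dependence of the bulk
density on the boundary rates, so `classify_phase()` probes each `(alpha,
beta)` node with perturbed runs (`delta = 0.05`) instead of matching
thresholds alone: LD tracks the alpha probe only, HD tracks beta only and
sits at `1 - beta` (tolerance 0.02 plus three standard errors), MC is
insensitive to both and matches `mf_rho_max()`, and a wide low-to-high
ramp flags a coexistence domain wall.  Ambiguity yields `"unclassified"`,
never a forced label.  `locate_transition()` brackets the first-order
LD/HD line by the largest adjacent-point density jump and refines it by
bisection; `mc_onset()` reports the smallest sweep alpha beyond which the
bulk density stops tracking alpha.  Scans default to a scaled geometry of
`Lx = 300` with warmup `100 Lx` and sampling `200 Lx` MCS, sizes at which
the classifier reproduces the analytic TASEP phase map in the unit-step
limit; stationarity is checked by comparing the first- and second-half
block densities within two standard errors.

## What the synthetic generators do and do not emulate

The deterministic seeded fixtures (`make_fixtures()`,
`single_motor_ensemble()`, `synth_tangent_profile()`,
`synth_geometric_dwell()`) generate every input the tests need at run
time: unit-step calibration runs, maximal-current and high-density runs,
single-motor trajectory ensembles, a congested dwell-time run, and
parameter-recovery targets with known ground truth.  They emulate the
*model's* stationary and dynamical behavior under controlled conditions;
they do not emulate biological dynein data -- no experimental step-size
mixtures, no ATP-concentration dependence, no motor detachment in the
bulk.  Green tests therefore certify the simulator and its estimators,
not agreement with any experiment.  The tangent-profile generator
defaults to `q = 3/Lx`, large enough that the tangent bending is visible
above its 1% noise; far smaller `q` makes the shape statistically
indistinguishable from flat and no estimator can recover it.

## Numerical choices

* The engine owns a 64-bit Mersenne-Twister stream seeded from the
  config; uniform variates are built from the top 53 bits, so runs are
  bit-reproducible across platforms and independent of R's RNG state.
  Probe and sweep runs derive their seeds deterministically from the
  template seed.
* Densities, currents and block summaries are accumulated in the sampling
  window only; injections/extractions are counted over the whole run for
  the exact bookkeeping invariant `Delta N = injections - extractions`.
* Block standard errors use 10 equal blocks; the maximal-current state
  carries long-range density fluctuations, so tests of its bulk density
  average a few independent realizations rather than trusting one run's
  block error.
* Degenerate inputs fail loudly: `Satt = Sdet = 0` (frozen secondaries),
  identically zero currents in `mf_rho_max()`, transverse hops with a
  single lane, non-convergent profile fits.

## Known limitations

* The quasi-2D low-load phase diagram retains a maximal-current phase at
  `Py = 0.025` (bulk pinned at `rho_max` and insensitive to both rates
  above the mean-field thresholds).  This is the behavior continuous in
  `Py` -- the `Py -> 0` limit is a stack of independent 1D lanes, which
  provably have an MC phase -- but it differs from reports that rare lane
  changes suppress the MC phase entirely; under this package's dynamics
  the onset of alpha-independence at `Py = 0.2`, `beta = 0.9` is near
  `alpha ~ 0.55`, as mean-field predicts.
* A single unobstructed motor's longitudinal MSD is strictly ballistic in
  its raw second moment and strictly diffusive in its variance (its
  increments have bounded length and sub-sweep memory), so no definition
  of the single-particle MSD produces a sustained `t^{3/2}` law here; the
  log-corrected fit of the variance at desk scale yields `xi ~ 1.1-1.3`.
* Under high load the entrance-side period-4 density oscillation is
  absent because the independent-site secondary kinetics load entrants
  within one sweep; the oscillation appears, with period exactly 4, under
  low-load (long-jump) conditions.
* Mean-field `J(rho)` is a factorization and is only accurate to ~10-15%
  at intermediate densities; the package always measures currents from
  simulation where it matters.

## Problem sizes

The test suite and the acceptance script run stationary measurements at
`Lx = 500` (1D, warmup 5e4 MCS, sampling 1e5 MCS), scans at `Lx = 300`
with `Ly = 4`, and single-motor ensembles of up to 1000 runs on a
500 x 4 cylinder -- sizes chosen so the full suite completes in minutes
on one CPU while keeping boundary layers small relative to the bulk
window.
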