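---
title: "The stemdish model: switches, lattice dynamics and pattern scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The stemdish model: switches, lattice dynamics and pattern scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemdish)
```

## The model

`stemdish` simulates a hypothetical adult tissue as a two-dimensional dish
of meshes, each holding at most one cell.  Four cell types interact:

* **S** (stem): divides, dies, moves, and can transform into P.  Its fate
  logic is a two-determinant *bistable* switch — the determinants X and Y
  repress each other's synthesis through a Hill function and degrade
  linearly.  At the default rates (synthesis 85 and 100, half-saturation
  45, Hill coefficient 4, degradation 1) the switch has two stable fixed
  points near (85, 7) and (3, 100); the x-dominant attractor is the S
  fate, the y-dominant one the P fate.
* **P** (progenitor): the transit-amplifying compartment.  Its switch adds
  self-activation, making it *tristable*: a balanced attractor near
  (79, 79) (remain P) flanked by an x-dominant attractor near (158, 0)
  (differentiate to A) and its mirror image (differentiate to B).
* **A**, **B** (terminal): do not divide; they die slowly and secrete the
  two signal species s1 and s2.

Signals diffuse on the lattice, decay at first order, and repress each
other's production (Hill kinetics with a very small half-saturation, 2
molecules).  Locally they feed back on the progenitor switch: the
self-activation rate of X gains an increment `eps = a*s1/b` (saturating at
`a = 10` above `b = 15` molecules), and symmetrically for Y.  High s1
therefore biases newborn progenitor daughters toward the A fate — the
mechanism by which an A-rich region defends its territory.

Everything is simulated exactly with the direct Gillespie method over 24
reaction channels (`reaction_channels()`): per-cell determinant synthesis
and degradation, division, death, S/P transformation and movement; and
per-mesh signal production, decay and diffusion.  At division the mother's
determinant counts are split binomially (p = 1/2, independently for X and
Y) between the daughters; each daughter's fate is the attractor basin its
counts fall into, evaluated with the local signal effect of the mesh it
occupies at birth.  This is the sole source of fate decisions — there are
no explicit division-type rates; the population-level rates (below) are
*emergent* from basin geometry and binomial noise.

## Fate calling and basin maps

Basin membership is decided by integrating the deterministic switch with a
fixed-step RK4 integrator until the trajectory is captured within a unit
distance of a stable fixed point (`classify_fate()`).  Non-convergent or
tied states are assigned P, favouring the dividing compartment; the set is
measure-zero.  Because the engine classifies daughters at every division,
it caches nearest-grid-point basin maps:

* stem map on `[0, 150]^2` at unit step;
* progenitor maps on `[0, 200]^2` at step 2, one per quantised signal
  effect pair.  The extent is 200 rather than 150 because the x-dominant
  attractor already sits near x = 158 at the defaults.  The `eps` pair is
  quantised to 6 levels per axis for the *map cache only* — the propensity
  functions always use the exact piecewise formula.  The quantisation and
  the coarser step misassign only states within one grid step of a
  separatrix, where the fate is borderline anyway; both are configurable
  (`eps_levels`, `prog_map_step`).

A practical caveat discovered during development: under a strong
one-sided signal effect (`eps_x = 10`, `eps_y = 0`) the balanced attractor
can disappear entirely (a saddle-node collision) — sustained signal
exposure forces differentiation.  Determinant re-sampling for a P cell in
such a mesh falls back to the signal-free basin.

## Density feedback and the mean-field model

The stem X-synthesis rate decreases with the number of dividing cells:
`iota_xs(n) = 85 * n0/(n0 + max(0, n - n0))`, anchored at the initial
dividing census `n0`.  Only the sign of the derivative matters for the
mean-field stability argument; this hyperbolic form is the package's
choice (configurable) since only monotonicity is prescribed.  It enters
the stochastic model solely through the X-production channel; daughter
classification uses the base switch, so the feedback shifts where mothers
sit in the phase plane rather than redrawing the basins.

The deterministic companion model (`mf_ode_rhs()`, `mf_steady_state()`,
`mf_stability()`) tracks the four average densities with per-capita rates
for three stem division types, six progenitor division types, reversible
transformation and death.  Its closed-form steady state fixes ratios (it
is scaled to a reference progenitor density), and the reduced 2-by-2
Jacobian in (n_P, n) coordinates has `det(J') = zeta * n * eta_S'(n)` and
a trace that is negative whenever the regime conditions hold, so the
fixed point is stable exactly when the density feedback slope is
negative.  The package implements the `mu_d` symbol consistently in both the
dynamical equations and the steady state, and a regression test confirms
the steady state zeroes the ODE.  The tissue regime of interest satisfies `eta_S - eta_P - gamma_S -
w_P < 0` together with `eta + eta_P + eta_S > gamma_S` and `lambda_P <
gamma_P + mu_d + mu_A + mu_B` ("limited capacity of proliferation");
`measure_effective_rates()` recovers all fifteen rates from a run's event
tallies, and the recovered rates from signal-free runs do land in this
regime.

## Division counters and termination

Each cell carries a division counter; a run terminates when the
arithmetic mean of the counters over living P cells reaches
`termination_divisions` (default 50).  Counters are inherited by both
daughters (+1 at a P division) and — deliberately — survive S/P
transformation.  Resetting them at transformation, which one might
equally well read into the verbal description, makes the metric
unreachable: the transformation rate per P cell (0.1645) is several times
the space-gated division rate, so counters would be wiped by churn faster
than divisions accumulate and the mean would hover near zero
indefinitely.  With lineage inheritance the counter measures rounds of
division along the ancestry, grows steadily, and termination
behaves as the model requires.  Two safety terminations exist
(dividing-cell extinction; `max_time`/`max_events`) because a stochastic
run on a small dish can otherwise fail to return.

## Space, movement and gating

Diffusion uses the orthogonal 4-neighbourhood (matching the unit-spacing
Laplacian); daughter placement uses the 8-neighbourhood to reduce
artificial blocking.  A dividing cell with no empty placement neighbour
contributes zero division propensity — gating the channel keeps the SSA
exact instead of drawing and discarding events.  Movement relocates a
dividing cell to a uniformly random empty mesh of the whole dish; it is
the model's pressure-release valve, not a mechanical model.

Two details of the signalling layer are implemented literally but
kept configurable, and they matter:

* the diffusion propensity is `D/h^2` per mesh per species holding at
  least one molecule — *not* multiplied by the count.
  `diffusion_scales_with_count = TRUE` gives the mass-action variant, in
  which a molecule hops at rate `D/h^2` to a uniform orthogonal neighbour
  and the mean-square displacement grows as `D * t` (verified in the test
  suite against random-walk theory).
* the diffusion target is a uniform orthogonal neighbour by default;
  `diffusion_neighbor_rule = "weighted"` implements the uphill variant
  (probability proportional to 1 + the neighbour's count), which moves
  molecules against the gradient.

## What the desk-scale experiments show — and what they cannot

The test suite and the reproduction script run reduced geometries chosen as
the package's working scale: circular dish radius 20 (inner radius 10),
termination at a mean of 20 progenitor divisions, 500 scoring shots, 3
seeds; the injury study uses radius 14.  At this scale a signal-free run
completes in seconds and reproduces pattern loss crisply: the final
similarity score falls below 10% of the initial pattern in every
replicate, while the four cell-type abundances stay homeostatic.

Pattern *maintenance*, however, is a genuinely scale-dependent
phenomenon, and the reduced dish sits below the scale at which the
default parameters can express it.  The measured mechanism: the
signalling length `sqrt(D/k) ~ 15` meshes is comparable to the whole
desk-scale dish, and the per-mesh diffusion propensity forwards a nearly
count-independent trickle of each species across the territory boundary,
so the *opposing* species sits at 15–30 molecules per mesh deep inside
each region.  That exceeds the saturation threshold `b = 15`, both signal
effects pin at `a = 10`, and the differential fate bias — the entire
maintenance mechanism — cancels.  Radius-20 signal-on runs hold a score
several-fold above the signal-free floor on intermediate horizons (0.37
vs 0.08 at 20 mean divisions) but decay toward the floor by 50; radius-30
behaves the same way, and the uphill-weighted variant condenses each
field into sparse spikes and performs worse.  Passing desk-scale tests
therefore demonstrate pattern *loss*, homeostasis, injury dynamics and
all structural properties; they do not certify the full-scale ~60%
maintenance plateau, which requires a dish whose regions are deep
compared with the signalling length (the radius-50 recipe is provided:
`experiment_recipe("signal_on", scale = 1)`, hours of compute).

## The similarity score

The target pattern defines two d-by-d filters from the *initial* state:
a template (+1 on the A region, -1 on the B region, 0 elsewhere) and a
penalty (1 outside the dish).  Each shot is encoded (+1 A, -1 B, 0
otherwise), zero-padded to 2d-by-2d (floor(d/2) left/top, ceil(d/2)
right/bottom for odd d), and both filters slide along the horizontal axis
with the vertical offset centred, giving d + 1 template responses `t_i`
and penalty responses `p_i`; the raw score is `max_i (t_i - p_i)`.  The
one-axis sweep matches the d + 1 responses per filter that the scoring
procedure defines; a full two-axis sweep is available
(`sweep = "full"`).  Raw scores are normalised by the initial
configuration's own raw score and clamped to [0, 1], so the series reads
directly as "similarity to the initial pattern" — a per-series min–max
normalisation would force every decaying series to end at 0 and was
rejected.  The sliding implementation is tested against an exhaustive
brute-force double loop on random instances.

## Numerical choices

* RK4 step 0.05 with capture radius 1.0 for fate classification (the
  switch dynamics have unit-scale relaxation rates; halving the step does
  not change any map at the defaults).
* Propensities are maintained incrementally per channel per mesh with
  Fenwick-tree prefix sums for O(log N) event selection; channel totals
  are rebuilt from scratch every 65,536 events to bound floating-point
  drift, and any drift-induced overshoot falls back to a clean rebuild.
* Snapshots are recorded on an adaptive grid whose spacing doubles when
  the ring exceeds twice the requested count, then thinned to exactly
  `n_shots` evenly spaced times; the final shot is always the exact final
  state.
* All stochastic draws (waiting times, event identities, binomial splits,
  placements) flow through R's own RNG, so `set.seed()` (or the `seed`
  arguments) makes whole runs bit-reproducible.

## Initial conditions

Built-in dishes fill the inner region with A cells and the outer region
with B cells, load the region meshes with 100 molecules of the matching
signal, and scatter dividing cells uniformly (defaults: 10% of meshes,
S:P = 1:2, the balance of the two transformation rates; the verbal
description prescribes uniform scattering but no densities).  S and P
determinants are drawn uniformly from their attractor basins.

## Known limitations

* One cell per mesh and teleport-style movement are deliberate
  simplifications; no mechanics, no pushing.
* The desk-scale maintenance caveat above: quantitative signal-on
  plateau values are only meaningful at full scale.
* The uphill diffusion variant implements one literal reading of an
  ambiguous verbal rule; at small scales it condenses the signal fields.
* Basin-map quantisation trades a sub-grid-step fate blur near
  separatrices for speed; exact per-birth integration can be recovered by
  shrinking `prog_map_step` and raising `eps_levels`.
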