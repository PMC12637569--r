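---
title: "Modelling spark initiation in RyR2 clusters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spark initiation in RyR2 clusters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ryrspark)
```

## The model

`ryrspark` simulates a cluster of cardiac ryanodine receptors (RyR2) as a
lattice of tetramers whose subunits are two-state, thermodynamically coupled
units. Subunit `i` of channel `c` has state `s = −1` (closed) or `+1` (open)
and flips with rates

* opening: `k_fo · [Ca] · γ_i`
* closing: `k_b / γ_i`

where the cooperativity factor is

```
γ_i = exp( δ (s_prev + s_next) + Σ_b w_b s_b ).
```

The first term couples the subunit to its two ring neighbours inside the
tetramer with the dimensionless mismatch penalty `δ = βJ`; the sum runs over
the subunit's inter-channel contacts `b` (at most two), each weighted by its
edge strength `w_b` (the coupling parameter `σ` by default). Because opening
is multiplied and closing divided by the same factor, every flip obeys
detailed balance at fixed calcium against the lattice energy

```
E(s) = −( δ Σ_ring s s' + Σ_inter w s s' + h Σ s ),   h = ½ ln(k_fo c0 / k_b),
```

which the test suite verifies exactly (stationary distribution vs Boltzmann
weights, and the Kolmogorov cycle criterion) using the master-equation
machinery described below.

A channel conducts when at least `open_subunit_min = 3` of its 4 subunits are
open — a majority rule that keeps channels reliably shut at diastolic
calcium. The dyadic cleft is treated as a single well-mixed compartment
(rapid-diffusion approximation), so all subunits see

```
[Ca] = c0 + g · n_open
```

with `n_open` the current number of conducting channels, including the
channel of the transitioning subunit ([Ca] is uniform in the dyad, so no
channel is excluded from its own feedback). This is the positive feedback of
calcium-induced calcium release: it is recomputed after every event.

A *spontaneous spark* is the first passage of `n_open` from the all-closed
state to the threshold `nc = 5`. The threshold only needs to exceed the
baseline open-channel fluctuations; the suite checks that `nc = 5` and
`nc = 10` give the same mean waiting time to within a few percent, because
once a handful of channels open together the feedback makes full activation
essentially certain. Spark termination (inactivation, store depletion,
resequestration) is much faster than the waiting times studied here and is
deliberately not modelled: runs end at threshold crossing.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `kfo` | 0.005 | (µM·ms)⁻¹ | Ca-binding rate constant; keeps channels almost always shut at ~0.1 µM resting calcium |
| `kb` | 0.3 | ms⁻¹ | subunit closing rate (≈3 ms mean open time) |
| `delta` | 0.5 | — | intra-tetramer mismatch penalty βJ |
| `sigma` | 0.5 | — | inter-channel contact strength (per-edge weight) |
| `g` | 25 | µM | dyadic [Ca] increment per open channel; 1–3 open channels give 25–75 µM, the range needed to sustain regenerative release |
| `c0` | 0.1 | µM | bulk (diastolic) calcium; sweeps use 2–120 µM |
| `open_subunit_min` | 3 | — | conduction rule |
| `nc` | 5 | — | spark threshold on the open-channel count |

Times are milliseconds, concentrations micromolar, rates ms⁻¹ throughout; no
unit-conversion layer exists.

### The σ convention

A genuinely open design question was whether the inter-channel term enters
the exponent as `δ·σ·s` (σ modulating the intra-tetramer penalty) or as
`σ·s` (σ an energetic coupling on the same βJ scale as δ). We adopt the
second: σ is the inter-channel analogue of δ, so `σ = 0.5` means a contact
exactly as stiff as an intra-tetramer interface and `σ = 1` a stiffer one.
Only this convention produces the orders-of-magnitude sensitivity of the
spark frequency to bond dilution and to σ itself that the acceptance script
measures (a ~10²–10³-fold frequency increase on full fragmentation at 2 µM,
and ≈4 decades of waiting-time change as σ goes 0 → 0.5 on the adjoining
lattice at 5 µM); under the first convention the same sweeps span barely more
than one decade. Users who want the other convention can simply build graphs
with edge weights `δ·σ`, since the engine reads per-edge weights and never
multiplies them by δ.

## Cluster geometries

Channels occupy sites of a rectangular grid (one ~30 nm tetramer per site),
addressed `(nx, ny)`, 0-based. Subunits sit at the four corners of the square
footprint, indexed in ring order 0 = NW, 1 = NE, 2 = SE, 3 = SW.

* **Adjoining**: laterally adjacent channels are joined by the two facing
  corner pairs of the shared edge (east: 1↔0 and 2↔3; south: 3↔0 and 2↔1).
  Interior subunits carry exactly two contacts — one horizontal, one
  vertical. A full `r × c` grid has `2·(2rc − r − c)` contacts (360 for
  10×10).
* **Oblique**: one diagonally facing corner pair per shared edge (east: 1↔3;
  south: 2↔0), pairing ring-opposite subunit indices in the staggered
  checkerboard pattern; every subunit has at most one inter-channel contact
  (180 contacts for 10×10).

The microscopy the geometries abstract does not pin down exact corner-index
pairings; any consistent convention with the stated per-subunit contact
counts (2 adjoining, 1 oblique) yields identical dynamics, because rates
depend only on signed sums of contact states.

Two disorder generators produce the structures seen in remodelled myocytes:

* `dilute_bonds(graph, p, seed)` keeps each inter-channel contact
  independently with probability `p` (intra-tetramer rings are structural and
  never broken) — a model of cluster fraying/fragmentation.
* `grow_preferential(n, rows, cols, alpha, seed)` places channels
  sequentially, drawing empty sites with weight `1 + ne^α` where `ne` is the
  occupied 4-neighbourhood count. We define `0^0 := 1` so `α = 0` is exactly
  uniform placement (R's `0^0` already follows this convention); the
  alternative linear form `1 + ne·α`, which is also uniform at `α = 0`, is
  available via `weight_form = "linear"`. The same 4-neighbourhood is used
  later for coupling. Ties need no special handling — the weighted draw
  resolves them stochastically.

## The stochastic engine

The Gillespie direct method is implemented in C++ with per-subunit
propensities. Waiting times are drawn from the exponential distribution with
the total-rate parameter, and events by weighted selection proportional to
individual subunit rates; both draws consume exactly one uniform each, so a
pure-R reference engine with the same draw structure reproduces the compiled
engine event-for-event on identical seeds (a test does this, and a
"paranoid" mode recomputes all propensities from scratch after every event
and checks the incremental bookkeeping to 10⁻¹⁰ relative).

Two structural facts keep updates cheap:

* a flip changes only the exponents of the flipped subunit's ≤ 4 neighbours
  (O(neighbourhood) work), and
* calcium multiplies *every* opening rate uniformly, so the totals factorise
  as `R_open = k_fo·[Ca]·Σ_closed γ_i` and `R_close = k_b·Σ_open γ_i⁻¹`, and
  a change of `n_open` is an O(1) rescale that never touches the γ factors.

Running sums are resynchronised from scratch every 2²⁰ events to bound
floating-point drift. Runs are censored at `t_max` (default 10⁸ ms) and
additionally capped at 10⁹ events (reported distinctly); censored runs are
returned as lower bounds, counted, and never dropped — an ensemble mean that
includes them is flagged as a lower bound. One seeded generator drives each
run; ensemble run seeds derive from a master seed by a fixed affine rule, and
morphology ensembles (dilution, growth) use a second, disjoint stream so that
cluster geometry and gating noise are separately reproducible. All seeds are
recorded in every result object and serialized output.

## The exact oracle

For clusters of up to 3 channels the full master equation is tractable:
`generator_matrix()` assembles the `2^(4M)`-state rate matrix (single-flip
off-diagonals with the calcium feedback evaluated in the source state),
`stationary_distribution()` solves the left null space densely,
`boltzmann_weights()` gives the closed-form equilibrium at `g = 0`, and
`mfpt_exact()` solves the hitting-time system `Q_tt τ = −1` for the mean
first-passage time from all-closed to `n_open ≥ nc`. The cap at 3 channels
(4096 states) is deliberate: the single-flip state graph is a
`4M`-dimensional hypercube, whose sparse factorisation fill-in grows
explosively, and 4096 states solve in seconds while 65536 do not. With
`g > 0` the chain is irreversible, but the solve never assumes detailed
balance, which is how the oracle can certify the feedback implementation:
the suite checks Gillespie ensemble means against `mfpt_exact()` to 3
standard errors on 1-, 2- (with `g = 25`) and 3-channel systems. Larger
clusters are validated statistically and by the R-vs-C++ engine
cross-check.

## Ensembles, sweeps, and the error protocol

`mean_waiting_time()` reports the ensemble mean of `T` and an error estimate
defined as the standard deviation of the means of 5 equal subsets (the
protocol used for all sweeps; with 50 runs these are 5 sets of 10). Waiting
times in the rare-event regime are near-exponential (the suite checks a
coefficient of variation within [0.7, 1.3]), so subset means based on fewer
than ~10 runs give unusable error bars — where a statement depends on error
bars the tests use the full 50-run protocol, and where only the mean matters
they use 10 runs. The acceptance script uses 50 runs for the fast
high-calcium point and σ = 0 baselines, and 10 runs for the slow diluted,
grown-morphology, and σ = 0.5 conditions; at the measured event throughput
this keeps the whole script under a minute while leaving Monte-Carlo errors
well inside the order-of-magnitude comparisons being made.

`sweep_waiting_time()` drives the four sweeps (bulk calcium `c0`, coupling
`σ`, bond survival `p`, compactness `α`). For `p` and `α` a fresh random
graph is generated per run from the recorded morphology stream, so the
reported mean averages over cluster realisations as well as gating noise.
Results serialize to CSV (one row per condition) and to a JSON mirror that
additionally carries every per-run time, censoring flag and seed.

## What the generators emulate — and what they do not

The geometry generators reproduce the *statistics* that matter to the
architecture question: contact counts per channel, bond-survival fractions,
and the dispersed-to-compact morphology continuum. They do not reproduce
mixed adjoining/oblique interfaces (noted as realistic but not simulated
here), off-lattice channel positions, 3-D stacking, or tethering-protein
maps. The gating model omits calcium-dependent inactivation, Mg²⁺
competition, luminal (store) regulation, buffer kinetics, and spatial
calcium gradients within the dyad. Passing tests therefore demonstrate the
internal consistency of this idealised model and the exponential
architecture-sensitivity *within* it — not quantitative agreement with any
particular imaging or sparks dataset.

## Numerical choices and degenerate inputs

* `t_max` defaults to 10⁸ ms; an all-rates-zero state (e.g. `kfo = 0` from
  all-closed) is reported as absorbing, not an error.
* Bond dilution draws one uniform per edge (`u < p`), so `p = 1` keeps every
  edge and `p = 0` none, exactly.
* `mfpt_exact()` refuses an empty absorbing set (`nc` unreachable) and a
  fully absorbing one (`nc = 0`), and returns 0 if the start state is already
  absorbing.
* The stationary solve replaces one balance equation with the normalisation
  row; probabilities within −10⁻¹² of zero are clamped to zero.
* Exponents are bounded by `±(2δ + 2σ)`, so γ never overflows for any sane
  parameter set.

## Known limitations

The oracle stops at 3 channels, so exact validation of larger clusters is
indirect. The mean estimator is sensitive to the heavy upper tail of `T` in
strongly coupled regimes: 10-run means of the slowest conditions scatter by
a factor ~2 around the converged value (the 50-run measurements in the test
suite show this directly), which is inside the order-of-magnitude precision
used for all slow-condition comparisons but would not support finer claims.
Spark termination and refractoriness are out of scope, so the model speaks
to spark *initiation* frequency only.
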