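# ryrspark

Stochastic simulation of cardiac ryanodine receptor (RyR2) cluster gating and
the timing of spontaneous calcium sparks.

## The problem

Calcium leak from the sarcoplasmic reticulum during diastole is driven by
spontaneous calcium sparks: rare, regenerative release events from clusters of
RyR2 channels in the dyadic cleft. Super-resolution imaging shows that these
clusters fragment and "fray" in disease, and that leak rises dramatically when
they do. `ryrspark` implements a subunit-resolved stochastic model of an RyR2
cluster to ask how cluster architecture — contact geometry, bond integrity,
and compactness — controls the mean waiting time `T` to a spontaneous spark
(equivalently the spark frequency `1/T`).

It is aimed at computational cardiac physiologists and biophysicists who want
a fast, exactly specified, reproducible sandbox for cluster-architecture
questions, with an exact master-equation oracle to validate the simulator.

## The model

Each RyR2 channel is a tetramer of two-state subunits `s_i = ±1` (closed /
open) on a ring. A closed subunit opens at rate `k_f γ_i` with
`k_f = k_fo [Ca]`, and an open subunit closes at rate `k_b / γ_i`, where the
cooperativity factor for subunit `i` of channel `c` is

```
γ_i = exp( δ (s_{i−1}^c + s_{i+1}^c) + σ' s_j^{c'} + σ'' s_k^{c''} )
```

with `δ = βJ` the intra-tetramer mismatch penalty and `σ', σ''` the coupling
strengths of the subunit's inter-channel contacts (a single `σ` by default).
A channel conducts when ≥ 3 of its 4 subunits are open. The dyadic cleft is
treated as well mixed (rapid-diffusion approximation), so every subunit sees

```
[Ca] = c_0 + g · n_open
```

where `n_open` is the number of conducting channels — the positive feedback
of calcium-induced calcium release. A spark is the first passage of `n_open`
to the threshold `n_c = 5` starting from the all-closed state; gating is
simulated exactly with the Gillespie direct method.

Cluster geometries: `adjoining` (two subunit contacts per adjacent channel
pair) and `oblique` (one contact, staggered) lattices; bond-diluted clusters
(each inter-channel contact kept with probability `p`); and heterogeneous
morphologies grown by preferential attachment (site weight `1 + n_e^α`).

Defaults: `k_fo = 0.005 /(µM·ms)`, `k_b = 0.3 /ms`, `δ = 0.5`, `g = 25 µM`,
`n_c = 5`.

## Worked example: fragmentation boosts spark frequency

```r
library(ryrspark)

params  <- rate_params(c0 = 2.0, sigma = 1)     # diastolic-range calcium
cluster <- build_adjoining(10, 10, sigma = 1)   # 100 channels, 360 contacts

# fully fragmented (p = 0) vs half-intact (p = 0.5) bonds, fresh dilution per run
frag   <- mean_waiting_time(function(s) dilute_bonds(cluster, 0,   seed = s),
                            params, n_runs = 10, master_seed = 1)
frayed <- mean_waiting_time(function(s) dilute_bonds(cluster, 0.5, seed = s),
                            params, n_runs = 10, master_seed = 1)
print(frag)
print(frayed)
spark_frequency(frag) / spark_frequency(frayed)
```

```
spark waiting-time ensemble: 10 runs, master seed 1
  mean T = 2034.59 ms (se 1968.29, sd of 5 set means)
spark waiting-time ensemble: 10 runs, master seed 1
  mean T = 752426 ms (se 575484, sd of 5 set means)
[1] 369.8
```

A cluster with only half of its inter-channel bonds broken waits hundreds of
times longer between spontaneous sparks than a fully fragmented one: the
spark frequency (here `1/T`, per ms) is exponentially sensitive to structural
integrity, rising ~370-fold on full fragmentation at 2 µM calcium. A single
run shows the spark itself:

```r
first_passage_time(build_oblique(10, 10, sigma = 0.5), rate_params(c0 = 6), seed = 1)
#> spark at T = 250.585 ms (1530 events, seed 1)
```

The `sweep_waiting_time()` helper repeats this over grids of `c0`, `sigma`,
`p`, or `alpha` and writes CSV/JSON; `mfpt_exact()` gives the exact mean
first-passage time for clusters of up to 3 channels as a ground truth; the
`inst/cli/ryrspark` script exposes `simulate`, `sweep`, `make-cluster` and
`oracle-check` subcommands for shell use.

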