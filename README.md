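# burstcoast

Event-driven simulation of fish schools with burst-and-coast (kick-and-glide)
locomotion and influence-based neighbor selection, parameterized for the
rummy-nose tetra *Hemigrammus rhodostomus*.

Many small fish do not swim continuously: they alternate a sudden
acceleration — a *kick*, at which the swimming direction is decided — with a
quasi-passive glide along a straight line. `burstcoast` models a school of
N such fish in an unbounded plane as asynchronous discrete-decision agents.
It is aimed at researchers in collective animal behavior who want to explore
how perception, attention (how many neighbors a fish reacts to) and
behavioral noise shape the collective states of a school — schooling
(aligned translation), milling (coherent rotation), swarming (cohesive
disorder) and dispersion (group break-up).

## The model

At the onset of its n-th kick, fish *i* turns by

    dphi_i = sum over its k most influential neighbors of dphi_ij + gamma_R * g_i,

where `g_i` is standard normal noise and the pairwise interaction decomposes
into attraction and alignment, each a product of decoupled functions of the
distance `d_ij`, the viewing angle `psi_ij` and the relative heading
`phi_ij`:

    dphi_ij = F_att(d) * O_att(psi) * E_att(phi)  +  F_ali(d) * E_ali(psi) * O_ali(phi)

    F_att(d) = gamma_att * (d/d_att - 1) / (1 + (d/l_att)^2)     (repulsive below d_att)
    F_ali(d) = gamma_ali * (d/d_ali + 1) * exp(-(d/l_ali)^2)

with empirically derived angular modulations (odd `O`, even `E`; see
`?interaction_kernels`). The *influence* of a neighbor is `|dphi_ij|`, and
each fish attends only to its k = 1 or 2 most influential neighbors — a
dynamical, topological selection quite different from nearest-neighbor
rules. Between kicks the fish glides with exponentially relaxing speed
(relaxation time 0.8 s); kick lengths (mean 7 cm) and durations (mean
0.5 s) are resampled at every kick.

The school's state is summarized by three order parameters sampled every
second: dispersion `D` (RMS distance to the barycenter, metres),
polarization `P` (norm of the mean heading unit vector) and the milling
index `M` (coherence of rotation around the barycenter), from which
`classify_phase()` assigns the collective phase.

## Worked example

```r
library(burstcoast)

cfg <- simulation_config(
  n_fish = 50,
  params = interaction_params(gamma_att = 0.04, gamma_ali = 0.2,
                              l_att = 0.28, l_ali = 0.28, k = 1),
  gamma_r = 0.2, n_kicks_per_fish = 600, transient_seconds = 50, seed = 2)
sim <- simulate_school(cfg, record_kicks = FALSE)
summary(sim)
#> Burst-and-coast school simulation: N = 50 fish, 600 kicks/fish
#>   k = 1, gamma_att = 0.04, gamma_ali = 0.2, gamma_r = 0.2, seed = 2
#>   300 snapshots every 1 s, final time 301.5 s
#> Post-transient means over 250 samples:
#>   dispersion   D = 0.213 m
#>   polarization P = 0.871
#>   milling      M = 0.137
#>   phase: Schooling
```

At these interaction strengths the 50 fish settle into a tight (D ≈ 0.2 m),
highly polarized (P ≈ 0.87), non-rotating (M ≈ 0.14) school. The
information-flow diagnostics show how concentrated the influence network is:

```r
dg <- diagnostic_series(sim)
keep <- dg$time > 50
sprintf("mean DMIN %.1f, mean DFNN %.1f, mean NN distance %.3f m",
        mean(dg$dmin[keep]), mean(dg$dfnn[keep]), mean(dg$mean_nn_dist[keep]))
#> "mean DMIN 18.9, mean DFNN 35.4, mean NN distance 0.037 m"
```

i.e. at a typical instant only ~19 distinct fish serve as someone's most
influential neighbor, while ~35 distinct fish are someone's nearest
neighbor: influence is concentrated on fewer individuals than proximity.

Phase-diagram experiments are built from `run_cell()` (replicated runs at
one parameter point), `sweep_phase_diagram()`, `cut_analysis()` (per-point
distributions of P and M along a cut, exposing the bistable
schooling/milling band), `cohesion_threshold_scan()` and
`optimal_attraction_scan()`. A thin command-line front end over these
functions is installed at `inst/cli/burstcoast.R`
(`simulate` / `sweep` / `diagnose` / `fixtures` subcommands).

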