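# pedbottleneck

Agent-based simulation of pedestrian evacuation through bottlenecks, built
for a question from crowd dynamics: how much of the behaviour observed at a
bottleneck — in particular the counter-intuitive *increase* of the density
in front of the door as the corridor leading to it gets wider — is
explained by simple physical interactions, without any social-psychological
ingredient?

The core is a collision-free speed model. Agents are hard discs of diameter
*l* = 0.35 m whose velocity is

    v_i = V(s_i) · e_i,        V(s) = min{ v0, max{ 0, (s − l)/T } },

where `s_i` is the headway to the nearest obstructing agent (forward
half-plane, lateral offset < *l*), `v0` = 1.34 m/s is the free walking
speed, and the slope factor `T` encodes motivation: `T` = 0.1 s for
highly-motivated, gap-closing crowds and `T` = 1.3 s for relaxed walking.
The desired direction `e_0` comes from a floor field — the Eikonal equation
`|∇c| = F` solved by fast marching, with slowness `F` ramping up within
0.25 m of walls — and is perturbed every step by white directional noise,
`e_i = (e_0 + ζ)/‖e_0 + ζ‖`, which both models imperfect steering and
dissolves the deadlocks a noiseless version would freeze into.

On top of the simulator sits the measurement suite used to characterise
bottleneck flow: exact (polygon-clipped) Voronoi densities, Gaussian-kernel
density fields that resolve lane formation, interaction-angle
distributions near the door, waiting-time power laws `T_w ∝ r^α` (α ≈ 1 for
single-file flow, α ≈ 2 for radially converging flow), and exit time-gap
statistics. Corridor and hopper (45° funnel) geometries are built in;
scenarios draw randomised initial densities from U(2.0, 3.0) m⁻² and size
the corridor as `l_c = max(N/(b·ρ_i), 7 m)`.

## A worked example

One low-motivation run in the widest corridor of the study design:

```r
library(pedbottleneck)

cfg <- scenario_config(b = 5.6, T = 1.3, dh = 0.02, max_time = 120)
run <- run_scenario(cfg, seed = 42)
run
#> <ped_trajectory> 55 agents, 1142 frames (dt = 0.01 s, stride 5), 55 exited
#>   first exit 0.95 s, last recorded exit 57.07 s

density_timeseries(run, window = c(10, 15))$mean
#> [1] 4.130837

fit_power_law(waiting_time_samples(run))
#> <ped_powerlaw> T_w ~ 6.02 * r^1.957 (se 0.035, n = 260, r in [0.3, 1.5] m)

exit_time_gaps(run$exits)$mean_gap
#> [1] 1.02501
```

Reading the numbers: all 55 agents leave within 57 s; the crowd in the
standard measurement rectangle in front of the door holds a mean Voronoi
density of 4.1 m⁻² during the 10–15 s window; the waiting time of an agent
grows almost quadratically with its distance to the door (α ≈ 1.96, the
signature of radially converging flow into a wide bottleneck); and once the
flow is established, one agent crosses the exit line about every second.

Replicated sweeps and the command-line interface (`inst/cli/pedsim run`,
`sweep`, `analyze`) wrap the same functions; `run_replicates()` returns one
metric row per seed and `summarize_sweep()` aggregates means with 95%
percentile intervals across replicates.

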