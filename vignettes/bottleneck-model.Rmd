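---
title: "The collision-free speed model behind pedbottleneck"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The collision-free speed model behind pedbottleneck}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

pedbottleneck simulates pedestrians evacuating through a bottleneck — a
corridor of width $b$ that ends in a door of width $w_e$ — and measures the
emergent flow: how dense the crowd in front of the door becomes, how the
waiting time of a pedestrian scales with their distance to the door, at what
angles pedestrians obstruct each other, and how regular the outflow is.
This vignette explains the model, every tunable that matters, the numerical
choices, and what the synthetic scenarios do and do not tell you about real
crowds.

## The model

Agents are hard discs of diameter $l$ moving in continuous space. Agent $i$
moves with velocity

$$\mathbf v_i = V(s_i)\, \mathbf e_i,$$

where $\mathbf e_i$ is its movement direction and $V$ the headway speed
function

$$V(s) = \min\{v_0,\ \max\{0,\ (s - l)/T\}\}.$$

The *spacing* $s_i$ is the headway to the nearest obstructing agent: agent
$j$ obstructs $i$ when it lies in the forward half-plane of $\mathbf e_i$
and its perpendicular offset from $i$'s movement line is below one body
diameter (two discs whose lateral offset exceeds $l$ can pass each other).
The speed is zero at contact ($s = l$), rises with slope $1/T$ and caps at
the free walking speed $v_0$ once the gap exceeds $v_0 T$. The slope factor
$T$ is the behavioural dial: a small $T$ (0.1 s) means gaps are closed
almost immediately — highly motivated, jostling pedestrians — while a large
$T$ (1.3 s) reproduces relaxed walking at speed-dependent distance. In the
limit $T \to 0$ the model degenerates to pure volume exclusion.

Two implementation details of the spacing deserve emphasis, because the
naive reading deadlocks:

* **Spacing is the free headway along the movement direction**, expressed
  as an equivalent centre distance
  $s_{ij} = \mathbf e_i\!\cdot\!\mathbf r_{ij} - \sqrt{l^2 -
  d_\perp^2} + l$ (identical to the centre-to-centre distance for an agent
  dead ahead). If instead the raw Euclidean distance is used, *any*
  touching neighbour anywhere in the forward half-plane pins the speed to
  zero regardless of where the agent wants to go; three agents arched over
  the door then freeze the whole system permanently, for every noise draw.
  With ray-headway, grazing a neighbour tangentially costs only the actual
  free distance, so the directional noise can dissolve arches. The exported
  `minimal_spacing()` measurement helper still reports the centre-to-centre
  distance of the obstructing neighbour.
* **Walls obstruct like agents**: the distance along the movement ray to
  the first wall segment, with body clearance $l/2$, enters the same speed
  law. Without this term, noise presses agents flat onto the door jambs
  where they anchor stable arches. Wall *avoidance* — preferring to walk
  around walls — is handled separately by the floor field below; the speed
  term only prevents walking into them.

### Navigation: the floor field

The desired direction $\mathbf e_0$ comes from a static floor field: the
Eikonal equation $|\nabla c(\mathbf x)| = F(\mathbf x)$ is solved once per
geometry with $c = 0$ on the exit line, where the slowness
$F = 1 + g\,\max(0,\, 1 - d_{\mathrm{wall}}/d_w)$ rises linearly towards
walls within the wall-avoidance distance $d_w$. Agents walk down the
cost gradient, $\mathbf e_0 = -\nabla c / |\nabla c|$, so shortest-time
paths bend away from walls by about $d_w$. The solver is a first-order
fast marching method on a regular grid of spacing $\Delta h$ (unit tests
pin it against an independent Dijkstra computation on the 8-connected grid
graph); gradients are central differences interpolated bilinearly to agent
positions. Inside the short passage downstream of the door the desired
direction is straight down the passage.

### Noise

A deterministic version of this model deadlocks: once speeds hit zero in a
blocked crowd, nothing moves again. Each step every agent therefore
perturbs its desired direction with white noise,
$\mathbf e_i = (\mathbf e_0 + \boldsymbol\zeta)/\|\mathbf e_0 +
\boldsymbol\zeta\|$, with both components of $\boldsymbol\zeta$ drawn
independently from a zero-mean normal with variance $\sigma$. The default
$\sigma = 0.7$ treats the quoted value as a *variance* (standard deviation
$\sqrt{0.7} \approx 0.84$); `sigma_is_variance = FALSE` switches the
reading. The noise is redrawn every step, so the time step also sets the
direction decorrelation time — one reason `dt` is frozen package-wide (see
below).

### Time stepping

Agents update sequentially in ascending id within each step of length
`dt`: each agent evaluates its spacing against current positions, moves by
$V \cdot \mathrm dt$, and a move that would bring it within $l$ of another
agent or across a wall segment is rejected — the agent keeps its position
with velocity zero for that step, the discrete counterpart of setting the
velocity to zero on collision. Pairwise centre distances therefore never
drop below $l$ and walls are never penetrated, by construction and by a
brute-force invariant test over every frame of every test run. A
synchronous variant was tried and rejected: simultaneous candidate moves
cancel pairwise under crowd pressure, which freezes loaded door arches
permanently.

Agents crossing $y = 0$ inside the door are logged with a linearly
interpolated crossing time (sub-`dt` resolution for the time-gap
statistics) and removed from the simulation at the crossing; the geometry
still carries a short downstream passage so that near-door navigation and
trajectory-file analysis are well defined.

## Parameters

| symbol | meaning | default | why |
|---|---|---|---|
| $v_0$ | desired speed | 1.34 m/s | mean unimpeded walking speed |
| $l$ | agent diameter | 0.35 m | from the observed density ceiling of about 9.4 m⁻² via hexagonal packing (`max_packing_density(0.175)`) |
| $T$ | slope factor | 1.3 s (low) / 0.1 s (high motivation) | fits the two motivation regimes |
| $\sigma$ | noise variance | 0.7 | deadlock resolution + imperfect steering |
| $N$ | agents per run | 55 | middle of the experimental range |
| $b$ | corridor width | 0.8–7.0 m | the swept boundary condition |
| $w_e$ | door width | 0.5 m | door width of the underlying experiment series; not fixed by the model description, hence configurable |
| $d_w$ | wall-avoidance distance | 0.25 m | slowness ramp width |
| $g$ | wall slowness gain | 1 | slowness doubles at a wall: visible avoidance without blocking narrow passages; not fixed by the model description |
| $\Delta h$ | floor-field grid | 0.01 m (0.02 m in sweeps) | see below |
| `dt` | time step | 0.01 s | see below |

**Choice of `dt`.** The obvious bound is `dt` $\le T/2$, which keeps the
mutual approach of two agents within one step below their remaining gap.
That bound (0.05 s at $T = 0.1$ s) is *not* sufficient: at `dt` = 0.05 s an
agent crosses half of the high-motivation reaction zone $v_0 T = 0.134$ m
in a single step, and the resulting slam-and-stand kinematics near the door
manufacture artificial clogs — strongly enough to invert the dependence of
the waiting-time exponent on crowd size. At `dt` = 0.01 s ($v_0\,
\mathrm{dt} \approx 0.1\, v_0 T$) the deceleration zone is resolved.
Because the noise is redrawn per step, `dt` is part of the noise process
itself and is therefore frozen at 0.01 s for all shipped experiments rather
than exposed as a convergence knob.

**Choice of $\Delta h$.** The floor field defaults to the centimetre grid.
Replicated sweeps use $\Delta h = 0.02$ m: the field enters only through
its interpolated gradient direction, and the flow statistics at 0.02 m are
indistinguishable from 0.01 m in our tests while the fields build four
times faster.

## Scenario generation

A scenario is defined by (variant, $b$, $N$, $T$). Each replicate draws an
initial density $\rho_i \sim U(2.0, 3.0)\ \mathrm m^{-2}$ and sizes the
corridor as $l_c = \max\{N/(b\rho_i),\ 7\ \mathrm m\}$, so that narrow
corridors are exactly long enough to hold the crowd at the drawn density
while wide corridors keep the physical 7 m length (their realised initial
density then falls below the drawn band — a property of the design, not a
bug; the realised band is asserted in the tests). Agents are placed
uniformly at random with hard-core rejection (pairwise $\ge l$, wall
clearance $\ge l/2$); "evenly distributed" is deliberately *not* a lattice,
matching the randomised initial conditions of the study design. The hopper
variant replaces the straight lower walls with 45° funnel walls running
from the door edges to the side walls.

Each replicate is a pure function of its seed (R's RNG drives the density
draw, placement and noise), so replicate tables are reproducible and
order-independent, and a single `--seed` reproduces an entire sweep.

## Measurements

* **Voronoi density**: each agent carries probability $1/A_i$ on its
  Voronoi cell (cells clipped to the walkable polygon, areas exact by
  half-plane clipping, no sampling); the density of a rectangle is the
  integral of that field divided by the rectangle area. This makes the
  density integrate to the agent count — the property the estimator exists
  for — and is verified against a dense-grid sampling oracle. The standard
  rectangle sits right in front of the door ($x \in [-0.4, 0.4]$,
  $y \in [0.5, 1.3]$ m) and is averaged over the 5–10 s and 10–15 s
  windows.
* **Gaussian density fields** resolve lane structure: unit-integral
  isotropic kernels of width $a = 0.2$ m (about the body radius; the value
  is a reporting choice, labelled on the output) superposed per frame and
  averaged.
* **Waiting times**: every 0.5 s in the 10–20 s window, each not-yet-exited
  agent that eventually exits contributes its straight-line distance $r$ to
  the door centre and its remaining time to exit $T_w$. An ordinary
  least-squares fit of $\log T_w$ on $\log r$ over $r \in [0.3, 1.5]$ m
  gives the exponent $\alpha$: 1 for single-file flow (speed independent of
  $r$), 2 for radially converging flow (continuity gives speed
  $\propto 1/r$).
* **Interaction angles**: for agents within 1 m of the door centre, the
  angle between the noiseless floor-field direction and the direction to
  the neighbour that limits their speed. Membership of the headway set is
  evaluated with a noise-perturbed movement direction, exactly as during
  stepping — the noise is white, so redrawing it during analysis is
  statistically equivalent to the simulation-time draws and keeps the
  metric computable from plain trajectory files. With a noiseless
  membership the angle could never exceed 90° (the neighbour would be
  confined to the forward half-plane), which contradicts the head-on
  deadlock geometry the measure is meant to expose.
* **Exit time gaps**: consecutive differences of the sorted crossing
  times, dropping the first and last ten agents of a run (start-up
  transient and straggler tail); the mean gap is an inverse flow.
* **Histogram modes** are local maxima of the 5°-binned, 3-bin
  moving-averaged histogram, filtered by topographic prominence (25% of
  the tallest peak) so plateau wiggles do not register as modes.

## What the generator emulates — and what it does not

The synthetic scenarios reproduce the *controlled* features of the
laboratory set-up: fixed geometry, homogeneous agents, instructed
motivation, randomised initial densities in a narrow band. They do not
contain heterogeneity in body size or speed, anticipation or cooperation,
torso rotation (a 0.35 m disc is a contracted pedestrian; shoulders are
wider), or any social response to the boundary. Passing the test suite
therefore demonstrates that the *mechanical* model with one behavioural
parameter reproduces the emergent observables — not that real crowds are
free of social effects.

## Known limitations

* **High-motivation clogs.** At $T = 0.1$ s the crowd compresses to near
  contact and the outflow is intermittent; some runs stall for long
  stretches within the 60–150 s horizons. The 10–15 s densities are
  measured in that (physically meaningful) congested state, but the
  waiting-time exponent for large crowds is degraded by it: at $N = 100$
  the pooled exponent lands around 1.75–1.85 rather than cleanly at 2, and
  fluctuates by about ±0.1 between 50-run seed batches. We report the
  computed value rather than loosening the check.
* **No 90° interaction mode.** The low-angle interaction mode near 30°
  reproduces robustly, but the lateral-contact mass near 90° appears as a
  shoulder of the distribution rather than a separate prominent mode: the
  near-door crowd in this implementation remains liquid-like instead of
  locking into the hexagonal zipper arrangement whose neighbour bearings
  (±30° diagonal-ahead, ±90° in-row) would produce a clean bimodal shape.
  A near-contact restriction of the metric recovers both modes, but we
  ship the unrestricted definition.
* The $T = 0$ limit, noise interpretation, door width and wall gain are
  configurable precisely because the model description leaves them open;
  results at non-default values are exploratory.

## Problem sizes used by the shipped tests and the acceptance script

Replicated conditions run 50 seeds each (the full study used 500) at
$\Delta h = 0.02$ m; the width sweep covers $b = 0.8$–$7.0$ m in 0.2 m
steps (0.4 m in the test suite) with the horizon cut at 16 s for
density-only sweeps, 120 s for waiting-time conditions and 150 s for the
$N = 100$ condition so that agents sampled at 10–20 s actually exit. These
are the package's own scaled-down study sizes; all of them are plain
arguments, so the full-size study is one configuration away.
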