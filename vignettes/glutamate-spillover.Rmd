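---
title: "Simulating glutamate spillover and astroglial uptake in stochastic neuropil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating glutamate spillover and astroglial uptake in stochastic neuropil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Excitatory synapses release a few thousand glutamate molecules into a
~120 nm wide, ~20 nm tall synaptic cleft. Whatever escapes the cleft
diffuses through the tortuous extracellular space (ECS) of the neuropil,
where perisynaptic astroglial processes expressing high-affinity
transporters (GLAST/GLT-1) compete with extrasynaptic receptors for it.
`neuropilsim` implements a particle-based Monte Carlo model of this
process with three ingredients:

1. **Stochastic geometry.** The tissue around the synapse is represented
   as randomly scattered, mutually overlapping spheres with radii uniform
   on [50, 300] nm, filling a 4 um cubic arena until the extracellular
   volume fraction `alpha` (the fraction of tissue volume not inside any
   sphere) reaches its target, 0.2 by default. The union of spheres forms
   irregular, interconnected extracellular voids tens to hundreds of nm
   wide -- qualitatively the geometry seen in 3D EM of cortical neuropil,
   without its anatomical detail. A disk-shaped cleft (radius 60 nm,
   half-height 10 nm) sits at the arena centre; no sphere surface may
   come within 10 nm of it, which keeps an escape corridor around the
   cleft rim open. A configurable share of spheres is labelled
   astroglial, calibrated so astroglia occupy ~10% of total tissue
   volume. Volume fractions are *measured*, not assumed: uniform test
   points are classified as ECS / astroglial / neuronal, and each
   generated geometry records its realized fractions with their binomial
   standard errors.

2. **Brownian dynamics.** Molecules perform a fixed-step isotropic random
   walk with step `delta` = 5 nm and step time `dt = delta^2 / (6 D)`
   (D = 0.5 um^2/ms), reflecting specularly off sphere surfaces, the
   arena walls, and the two cleft membranes. Multiple reflections within
   one step are resolved sequentially (up to 8, then the step is
   rejected; rejections are counted and are a few per million steps).
   Both neuronal and astroglial membranes are impermeable; they differ
   only in what happens nearby.

3. **Transporter binding.** While a free molecule is within 5 nm of an
   astroglial surface, a binding hazard applies, governed by the time
   constant `Psi` that lumps transporter affinity, surface density, and
   proximity into one parameter. Binding is irreversible on the simulated
   time scale (a few ms), since transporter unbinding takes tens of ms.
   A per-molecule clock accumulates time inside the proximity shell and
   resets once the molecule departs by more than the shell width.

### The binding law, and an ambiguity

The package provides two discretizations of the first-order lifetime
expression `P(t) = 1 - exp(-t/Psi)`:

* `binding_law = "hazard"` (default): a constant per-step probability
  `1 - exp(-dt/Psi)`. This is the memoryless process whose *lifetime CDF*
  is exactly `P(t)`: a molecule clamped inside the shell binds after an
  exponentially distributed time with mean `Psi` (verified by a KS test
  in the test suite).
* `binding_law = "episode"`: the probability `1 - exp(-t/Psi)` is
  evaluated afresh at every step at the current proximity-episode age
  `t`. This reads the lifetime expression as a per-evaluation
  probability; it is an accelerating-hazard law that binds roughly 3-4x
  more molecules at `Psi` = 1 ms than the hazard law.

The distinction matters because shell episodes are extremely short
compared with `Psi`: with `delta` = 5 nm, `dt` is ~8.3 ns, and a molecule
rattling against a surface leaves the 5 nm shell within a few steps. Under
either law, the per-episode binding probability at `Psi` = 1 ms is of
order 1e-5 to 1e-4, so a few percent of released molecules are captured
within 3 ms. Published observations of near-complete perisynaptic capture
on this time scale imply an effective binding one to two orders of
magnitude stronger than any reading of the lifetime law we tested
(including non-resetting and absolute-time clocks, which overshoot in the
opposite direction by binding everything within 0.3 ms). We keep the
hazard law as the default because it alone has the stated exponential
lifetime semantics; the comparison is reproducible via the
`binding_law` switch.

## Parameters that matter

| parameter | default | units | meaning |
|---|---|---|---|
| `arena_edge` | 4 | um | edge of the cubic simulation arena |
| `alpha_target` | 0.2 | -- | extracellular volume fraction (0.1-0.3 physiological) |
| `astro_fraction_target` | 0.10 | -- | astroglial share of tissue volume |
| `radius_min`, `radius_max` | 50, 300 | nm | sphere radius range |
| `cleft_diameter`, `cleft_height` | 120, 20 | nm | synaptic cleft disk |
| `cleft_exclusion` | 10 | nm | sphere-free clearance around the cleft |
| `n_molecules` | 1000 | -- | released glutamate molecules |
| `D` | 0.5 | um^2/ms | free-medium diffusion coefficient |
| `psi` | 1 | ms | binding time constant (larger = weaker uptake) |
| `step_length` | 5 | nm | random-walk step; must not exceed the shell |
| `binding_shell` | 5 | nm | astroglial proximity shell |
| `duration` | 3 | ms | simulated window (unbinding ignored, so <= ~5) |

`step_length <= binding_shell` is enforced so a step can never jump the
proximity shell. The walk reproduces free diffusion exactly in the mean
square (`MSD = 6 D t`, tested), and in crowded geometry the effective
diffusivity drops below `D` (hindrance emerges from the geometry; no
tortuosity factor is imposed).

## Geometry calibration choices

The construction loop adds spheres in batches (rejecting candidates that
violate the cleft exclusion, checked analytically against the cleft
cylinder) and measures `alpha` on a fixed set of 2e5 calibration points;
because a fixed point set makes the measured fraction exactly monotone in
the sphere count, the final count is set by a prefix binary search, which
centres the realized `alpha` on its target to within ~0.002 -- well inside
the 0.01 tolerance. Astroglial labels are thresholded from fixed uniform
marks, with the threshold bisected against the measured astroglial
fraction; a test point covered by both kinds counts as astroglial,
favouring the binding surface (configurable consequence: the astroglial
fraction is an upper-bound attribution under overlap). Each trial draws a
fresh geometry: the model treats the neuropil statistically, and
trial-to-trial geometry variation is part of the predicted variance.

## Analysis conventions

Radial profiles are binned in concentric spherical shells centred on the
cleft centre, starting at the cleft boundary (60 nm), 25 nm bins by
default (5 nm for onset measurements). Counts convert to concentration
via `C = n / (N_A V_ecs)`, with the ECS shell volume estimated by test
points; shells with no estimated ECS volume report missing, never zero.
Bound glutamate is a surface-bound species re-expressed volumetrically
with the same ECS denominator, so free/bound concentration ratios reduce
to count ratios bin by bin. The length constant `lambda` is the distance
over which a profile decays to 1/e of the concentration in the first bin
beyond the boundary, located by linear interpolation between bracketing
bins and measured from the reference bin's centre (an exactly exponential
profile then returns its true constant, to <2% at bin widths up to
lambda/10). Profiles that never decay to 1/e within the profiled range
-- common for nearly flat free-glutamate profiles at 3 ms -- are flagged
undefined and masked, not zeroed.

"Near the synapse" is operationalized as the first 50 nm beyond the cleft
boundary. The near-field space average uses molecules within 0.3 um of
the cleft centre: with 1000 released molecules the whole-arena ECS
(~12.8 um^3) caps the global average at ~0.13 uM, so only the sub-micron
field can carry micromolar averages.

## Seeds and reproducibility

Every stochastic component takes an explicit seed; a geometry is
bit-reproducible from `(params, seed)` and a recording from
`(geometry, seed)`. The compiled stepping loop consumes R's RNG stream in
exactly the order of the R-level `propose_step()` / `resolve_motion()` /
`update_binding()` composition, and the test suite asserts bit-identical
trajectories between the two paths. `run_trials()` derives per-trial
seeds from one `seed_root` by a single `sample.int()` draw, so any trial
is reproducible in isolation. In `sweep_psi_alpha()` the default
`paired = TRUE` reuses the same trial seeds in every (Psi, alpha) cell --
common random numbers, so that grid contrasts are not drowned by
trial-level noise; `paired = FALSE` gives every cell its own stream.

## Problem sizes used in the tests

The test suite exercises full default-scale runs (1000 molecules, 3 ms,
5 trials) once, in the reproduction checks; all other tests run on
reduced problem sizes (2-3 um arenas, tens to hundreds of molecules,
sub-millisecond windows) chosen so that each property is still sharply
testable: closed-form oracles are deterministic, and stochastic checks
are sized to 3-4 standard errors of their sampling noise.

## What the generator does and does not emulate

Passing tests demonstrate correct Brownian kinematics, reflection,
binding bookkeeping, calibration, and estimator algebra *within this
model world*: overlapping spheres with uniform radii, a single synapse,
impermeable membranes, no receptor interactions, no transporter state
cycle, no electrodiffusion or bulk flow. Real neuropil differs in known
ways (non-spherical processes, correlated astroglial coverage, multiple
release sites, dead-space microdomains), so quantitative agreement with
tissue measurements is calibration, not prediction. In particular the
model's free-glutamate tail at 3 ms is micromolar only within a few
hundred nm of the synapse, and the spatial reach of *bound* glutamate is
set jointly by `Psi` and the astroglial density, trends the sweep module
quantifies (`lambda_bound` grows with `Psi` and with `alpha`).

## Known limitations

* Binding strength at `Psi` ~ 1 ms is weak under both provided readings
  of the lifetime law (see above); reported free/bound ratios near the
  synapse are accordingly much higher than published estimates that
  assume near-complete capture.
* Shell membership is evaluated at step endpoints; a molecule that
  touches the shell mid-step and leaves it within the same step is not
  credited, a bias bounded by one step time per episode.
* The bound-count series is recorded at a fixed stride (~512 samples per
  run), so binding times are exact per molecule but the series is a
  subsample.
* Geometries are generated fresh per run by design; there is no library
  of frozen reference geometries.
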