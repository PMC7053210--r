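---
title: "eprsim: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{eprsim: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eprsim)
```

## The model

`eprsim` simulates contrast-agent biodistribution for fluorescence-guided
surgery as a frame-stepped particle system. The world is deliberately
abstract: an axis-aligned reflective box is the imaging field of view
(FOV, normal tissue), a sphere inside it is the tumor region of interest
(ROI), and an optional concentric shell around the ROI is the enhanced
permeability and retention (EPR) zone. Coordinates are dimensionless
chamber-lengths and the time unit is the frame; none of the quantities are
calibrated to physical units, and delay/rate settings are relative
arbitrary units. The model is a qualitative, reproducible illustration of
how uptake and clearance kinetics shape imaging contrast — not a
pharmacokinetic or optical simulation.

Each frame applies, in fixed order: **release** (batches of `batch_size`
particles activated at the injection site every `release_cadence` frames,
with uniform-hemisphere directions into the chamber), **motion** (each
active particle independently advanced along its straight trajectory),
**clearance** (scheduled removal of randomly selected particles per
compartment), **sampling** (the distribution chart row, every
`sample_cadence` frames), then the frame counter increments.

Motion resolves surface crossings continuously within the frame: walls
reflect specularly; the ROI sphere passes entering particles through
(recording first uptake, which switches emission on in responsive mode)
and reflects particles hitting it from inside — a one-way trap, so no
off-reversion rule is needed; the EPR sphere, when enabled, passes
entering particles through and gives in-zone particles hitting it a
Bernoulli escape (probability `epr_escape_prob`) back into the FOV,
otherwise reflecting them inward. Particles never interact with each
other.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `n_particles` | 2000 | count | dose; large enough for smooth curves, small enough for ~1 s runs |
| `batch_size` / `release_cadence` | 100 / 5 | count / frames | the stated release schedule |
| `base_speed` | 0.02 | chamber-lengths/frame | all phases (release, uptake, clearance) complete inside a 6000-frame run |
| `viscosity_epr` | 0.9 | fraction | in-zone speed is `1 − 0.9 = 0.1×` FOV speed |
| `viscosity_roi` | 0.155 | fraction | in-ROI speed is `0.845×` FOV speed |
| `epr_escape_prob` | 0.5 | probability | the 50% escape rule at the zone boundary |
| `attraction_strength` | 0.2 | radians/frame | see below; the funnel is stated qualitatively, not quantified |
| `fov_clear_cadence` / `roi_clear_cadence` | 20 / 40 | frames | the stated clearance cadences |
| `sample_cadence` | 30 | frames | the stated chart-update cadence |
| `fov_delay`/`fov_rate`, `roi_delay`/`roi_rate` | 250/25, 750/10 | frames, particles/event | the moderate-clearance preset (`sim2`) as the neutral default |
| geometry | box (1, 0.6, 0.6); ROI r = 0.15; EPR r = 0.30 | chamber-lengths | no absolute dimensions exist; relative FOV:ROI size is user-selectable |

Interpretation choices where the source material is loose:

* **Rate semantics.** Printed rates (50, 25, 10) are particles removed per
  clearance event. The first event fires exactly at `delay`, then every
  `cadence` frames. This reproduces the fast-vs-slow clearance orderings
  of the presets and makes event logs exact arithmetic progressions.
* **Attraction.** The "gravity-like" funnel is a bounded per-frame
  rotation of the direction vector toward the ROI centre, capped at
  `attraction_strength` radians, preserving the speed norm so the
  viscosity multipliers stay exact invariants. 0.2 rad/frame makes most
  zone-entering particles reach the ROI (the documented behaviour) while
  leaving boundary collisions — and hence the escape rule — active.
* **Release directions** are uniform on the interior hemisphere at the
  injection site (the exact distribution is unspecified); speeds carry no
  frame-to-frame jitter.
* **EPR particles count as FOV** both for clearance (stated) and in the
  distribution chart (unstated; the chart choice keeps the paired
  always-on/responsive runs' series identical, as documented).
* **Injection/clearance sites are points**; the original's tube meshes are
  rendering geometry with unspecified extents.
* **Escape coin-flips are re-rolled per collision**, independently.

## Determinism

A single RNG stream seeded from `config$seed` drives everything, consumed
in a fixed order per frame: release directions (two uniforms per released
particle), escape coin-flips during motion in particle-index order, then
clearance selections (FOV before ROI). Two runs with the same config are
bit-identical; always-on and responsive twins consume identical streams,
so their trajectories and distribution series match exactly and only
emission flags differ. Because particles are independent and motion
consumes randomness only at EPR boundary hits, a particle's trajectory is
unchanged whether it is stepped alone or alongside others — the
non-interaction property the tests verify directly.

## Numerical choices

* Collision resolution tracks the remaining fraction of the frame and
  rescales the leftover displacement by the new region's speed multiplier
  after every crossing, capped at 256 sub-steps per particle per frame.
* Crossing parameters below `1e-12` are rejected as immediate re-hits;
  after every surface event the particle is nudged `1e-9` chamber-lengths
  to the correct side of the surface. Together these make grazing
  contacts resolve on the next frame rather than twice in one.
* The chart denominator is the total administered dose, not the particles
  currently present, so FOV and ROI curves can both decay to zero as the
  dose clears. Frame 0 is always sampled (the chart origin), and a
  terminal sample is taken at `max_frames` when it lies on the cadence, so
  a run of F frames yields `floor(F / cadence) + 1` samples.
* `summarize_distribution()` breaks peak ties by the earliest frame. The
  crossover is the first sample with `pct_roi >= pct_fov`, except that
  samples with both percentages exactly zero never count: equality with no
  signal is vacuous, not contrast. The contrast window is the first
  maximal run with `pct_fov == 0` and `pct_roi > 0`.

## TBR analysis

The in vivo quantification arithmetic operates on already-summarised total
radiant efficiencies (TRE): TBR is the tumor TRE over the mean of three
equal-area background TREs, threshold analysis uses TBR ≥ 2 (the
conventional clinically relevant contrast level) with maximal runs
reported at sample resolution and no interpolation between acquisition
times, and fold-change is a plain ratio between two sampled times.
A zero mean background makes the ratio undefined and is an error, not a
silent `Inf`.

### The synthetic generator

`synth_timecourse()` exists to exercise this arithmetic without animal
data. Its functional form is a modelling choice (no model is fitted to
real data): tumor
`A (1 − e^{−k_up s}) e^{−k_tum s}` with `s = max(t − delay, 0)`, and
backgrounds the same shape with a faster clearance rate, each observation
multiplied by unit-mean lognormal noise of coefficient of variation
`noise_cv`. Defaults encode the documented qualitative profile of a
well-retained off-to-on probe: complete silence for the first hour
(`onset_delay = 1`), a tumor peak near 24 h (`k_up = 0.10/h`,
`k_tum = 0.01/h` put the noise-free argmax at ~24 h), and a background
amplitude of `amplitude / 1.1` with `k_bg = 0.036/h` so the noise-free
TBR is 1.1 just after onset and crosses 2 exactly at the 24 h sample,
rising thereafter because tumor clearance is slower than background.

What the generator does **not** emulate: the unbounded exponential growth
of its TBR tail overshoots real late-study ratios (where the
clearance-rate contrast diminishes); there is no plateau, no inter-animal
variability, no autofluorescence floor unless `baseline` is set, and no
connection between the particle engine and these curves. A green TBR test
therefore establishes the correctness of the ratio/threshold/fold-change
arithmetic on controlled input — not any biological claim.

## What green tests establish — and what they do not

The property suite checks conservation, determinism, monotone lifecycle
flags, exact speed multipliers, clearance schedules, the escape
probability (binomially), the funnel property, and the documented
contrast phenomenology of the presets (peak-while-background-dominates
for fast clearance; a contrast window for slowed clearance; higher and
earlier tumor contrast with the EPR zone on). These validate the engine
against its own stated rules. They do not validate the model against
tissue: motion is not blood flow, there is no photon transport, and
frames are not hours. The simulation's value is the reproducible,
inspectable interplay of its kinetic parameters.

## A complete run

```{r example, eval = FALSE}
run <- simulate_biodistribution(sim_preset("sim5", seed = 1))
glance(run)       # peak, crossover, contrast window, detectability onset
autoplot(run)     # distribution curves with the window shaded

cfg <- sim_preset("sim6")
write_sim_config(cfg, "sim6.json")   # lossless JSON round-trip

tc <- synth_timecourse(seed = 1)
tc |> dplyr::filter(time_h > 1) |> tbr() |> tbr_crossings(threshold = 2)
```
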