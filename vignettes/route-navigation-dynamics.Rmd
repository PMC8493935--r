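---
title: "Modeling route navigation: heading dynamics, trajectory comparison, and model fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling route navigation: heading dynamics, trajectory comparison, and model fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(routenav)
```

## The model

`routenav` studies goal-directed steering through planar obstacle fields
with a dynamical perceptual-motor primitive (DPMP) model of heading
direction. An agent moves at constant forward speed; all behavioral
structure lives in the angular acceleration of its heading $\phi$:

$$
\ddot\phi \;=\; -\beta\,\dot\phi
\;-\; \gamma\,(\phi-\theta_g)\left(e^{-c_1 d_g} + c_2\right)
\;+\; \sum_{i}\varepsilon\,(\phi-\theta_{O_i})\,
  e^{-c_3\lvert\phi-\theta_{O_i}\rvert}\,e^{-c_4 d_{O_i}}
$$

The three terms are damping on the turning rate ($\beta$, 1/s), a
point-attractor pull toward the goal bearing $\theta_g$ whose stiffness
($\gamma$, 1/s²) decays with goal distance $d_g$ but never below the
fraction $c_2$, and a repeller pushing the heading away from each obstacle
bearing $\theta_{O_i}$ ($\varepsilon$, 1/s²) that decays exponentially in
both the angular offset and the obstacle distance. Trajectories are not
planned; routes emerge from the interplay of the attractor and repellers
as the agent moves.

Angle conventions: headings are world-frame, counterclockwise from $+x$,
in radians; every angular difference in the model is wrapped to
$(-\pi,\pi]$ before use, since unwrapped differences make both the
stiffness and the exponential repulsion meaningless after a full turn.
The wrap is implemented with floored modulo identically in the R helpers
and the compiled core, so the two paths agree bitwise.

The shaping constants $c_1{=}0.4$/m, $c_2{=}0.4$, $c_3{=}6.5$/rad,
$c_4{=}0.8$/m are the classic values of the original point-attractor
steering formulation. They ship as configuration (`dpmp_constants()`) and
stay fixed during fitting; only $(\beta,\gamma,\varepsilon)$ are free.

## The task environment

The navigation game is a 40 × 40 m walled square. Trials start at
$(\pm5,-16)$ and end at a target at $(\pm12,16)$ or $(0,16)$; crossing a
start with a target on the same side gives a *near-side* route, opposite
sides a *far-side* route, and the centered target a *middle* route.
Obstacles are 0.5 m wide discs. The game kinematics are deliberately
stiff: 10 m/s forward speed, a 25°/s rotation-speed cap reached at
62.5°/s², 50 Hz updates, discrete controls (move forward / stop; rotate
left / none / right) with decisions taken every fifth frame, and episodes
of at most 30 s ending at first contact with the target (+1) or an
obstacle (−1). Agents observe 11 rays spanning ±45° in 9° steps, each
classified one-hot over (target, obstacle, other, nothing), plus the
egocentric target bearing and distance — 46 inputs in all.

Two conventions deserve a note. The rotation cap is a *speed*, so its
units are per second (25°/s), and the five rays on each side spread over
45° per side, giving 9° spacing; both are configurable in
`kinematics_spec()` and `cast_rays()`. The maximum ray length defaults to
the field diagonal so the wall is always within reach, and the "other"
class fires only on walls because the scene contains nothing else.
Rotation decays toward zero at the same 62.5°/s² when no key is held;
instant stop is a plausible alternative the environment does not use.

## Integration and numerics

`dpmp_simulate()` integrates the model with a first-order scheme at
`dt = 0.02` s (the game's own update interval): the angular acceleration
is evaluated at the current state, then the turning rate, heading, and
position are updated in sequence. The model is non-stiff at the task's
scales, and a first-order method at 50 Hz matches what the game itself
does; the convergence test in the suite confirms the endpoint error
shrinks with `dt`. Two modes exist because the analyses need both:
`"continuous"` integrates the raw dynamics (used for fitting),
`"game"` clamps $|\dot\phi|$ and $|\ddot\phi|$ to the keyboard caps.
Simulations are bitwise deterministic; a candidate parameter set that
drives the state non-finite raises an error naming the failing step, and
the fitting objective converts that into a large finite penalty so a
differential-evolution population can move out of unstable regions.

Termination uses disc contact: the agent body is modeled as a 0.25 m
disc, symmetric with the cylinders (a package convention; configurable),
so capture and collision both trigger at 0.5 m center distance.

## Preprocessing and comparison statistics

Raw 50 Hz trajectories are linearly resampled to 1,000 points (headings
via unwrapped interpolation), filtered by the two admissibility rules —
discard a trial longer than 1.2× the mean cumulative path length of its
scenario (mean taken over the full pool, before any discards) and discard
a trial lasting over 20 s — and reduced to one x-value per 20 cm bin of y
over $[-16, 16)$: exactly 160 points. Bins average all visits — the
simplest symmetric treatment of the rare backtracking trial — and empty
interior bins are filled by linear interpolation and boundary bins by
nearest-value extrapolation.

All comparison statistics act on that fixed grid:

* `trajectory_distance()` — mean over bins of $|x_a - x_b|$, a
  pseudometric, reported in meters;
* `ci_band()` — per-bin 2.5th/97.5th empirical percentiles, with the
  linear-interpolation percentile definition (R's type 7) fixed and
  documented so results reproduce bit-exactly;
* `ci_containment()` — the fraction of bins in which a reference (e.g. a
  group mean) lies inside a band, computed over bins rather than
  time-steps since the band itself is built per bin;
* `route_signature()` / `preferred_routes()` — an automated replacement
  for by-eye route identification: each obstacle is labeled by the side
  of the travel direction it lies on at closest approach, obstacles never
  approached within 3 m are dropped so far-off obstacles cannot split
  routes spuriously, and signature groups holding at least 10% of a
  population's trajectories count as preferred routes;
* `aggregate_distances()` — all between-group pairs, and within-group
  pairs excluding same-participant pairings, averaged per participant and
  route type into a tidy table whose Player × Location structure is ready
  for external mixed-model tools (`lme4` and friends); the package
  deliberately does not run that inference itself.

## Model fitting and validation

`fit_dpmp()` is the package's central modelling interface. It searches
$(\beta,\gamma,\varepsilon)$ with an in-package rand/1/bin differential
evolution (dithered mutation in $[0.5,1]$, crossover 0.7, population 30,
up to 60 generations by default — all configurable), minimizing the
dynamic time warping distance between the observed $(x,y)$ sample path
and the path simulated under the candidate parameters. The DTW is the
classic boundary-anchored dynamic program with Euclidean local cost and
symmetric (match/insert/delete) steps, computed in compiled code on the
raw sample sequences; binned series can be compared instead by passing
binned coordinates explicitly. DTW on 2-D positions rather than a 1-D
series, and no pre-normalization, are deliberate choices: the compared
paths live in the same metric space and units.

Search bounds default to $\beta\in[0.1,20]$, $\gamma\in[0.5,400]$,
$\varepsilon\in[1,1000]$ — wide brackets around the magnitudes the task
produces. The fit returns a classed object with `coef()`, `predict()`
(re-simulation in the fitting scenario or new ones), `residuals()`,
`plot()` and `summary()` methods. `characteristic_params()` averages an
agent's fits into its characteristic parameter set, and
`simulate_characteristic()` re-simulates those per scenario.

Because fitted parameters are only as credible as their identifiability,
`recovery_study()` simulates trajectories at known parameters, refits
them, and reports relative errors. On the shipped obstacle-flanked
far-side scenario, noiseless recovery has median relative errors below 1%
for all three parameters; identifiability degrades when a scenario's
route passes no obstacle closely (then $\varepsilon$ is weakly
constrained), which is why the validation scenario places obstacles along
the path. $\varepsilon$ estimates are strongly right-skewed across
agents; `boxcox_transform()` (maximum-likelihood $\lambda$ via the
profiled likelihood) is applied to $\varepsilon$ before descriptive
summaries in `summarize_params()`.

## The synthetic-data generator

The generator exists so every pipeline stage is testable without
external data. It emulates the task design — random obstacle
configurations (default 9 obstacles, a package choice, rejection-sampled
with 1.5 m clearance from walls, starts, targets and each other), the
2 starts × 3 targets crossing, six repetitions per scenario, and a
restart rule: a trial that does not reach the target is re-run with fresh
trial-level parameters up to a cap, mirroring a game that only records
successful trials. Episodes run to the 30 s episode cap while the 20 s
discard rule stays in preprocessing, so slow successes are generated and
then filtered out exactly as the admissibility rules dictate.

Two population profiles ship. Both act through the discrete keyboard
interface via `scripted_dpmp_policy()` — trained navigation agents in
this task emit the same five discrete outputs as human players — and
differ in their variability structure: *human-like* agents draw
characteristic parameters log-normally with 30% between-agent and 15%
within-agent (trial-to-trial) coefficients of variation and carry 0.05
rad/s of decision noise; *drl-like* agents use 5%/2% CVs and 0.01 rad/s
noise. Log-normality is a modelling choice (positive support, scale-free
spread), not an empirical claim about any real population.

Three generator choices required judgment, and all three trace to the
same geometric fact: at 10 m/s under a 25°/s cap the minimum turning
radius is 22.9 m, while the capture window is 0.5 m.

* **Parameter means.** The walking-scale magnitudes of the original
  steering formulation ($\gamma\approx7.5$, $\varepsilon\approx198$)
  cannot complete far-side routes at game speed — the goal attractor is
  too weak to reacquire a missed target and the repulsion acts only
  ${\sim}3$ m out, inside the unrecoverable zone. The shipped means
  $(\beta,\gamma,\varepsilon) = (3.25, 30, 600)$ put the dynamics in a
  regime that completes all route types — the same regime that fitting
  the model to game-speed trajectories lands in. They are generator
  knobs, not estimates of anyone's data.
* **Initial heading.** Trials start facing the target. Players could
  rotate in place before moving off, and a $+y$ start heading makes
  far-side routes geometrically impossible under the caps.
* **Stop-and-turn.** The scripted policy releases forward motion while
  the desired turning rate exceeds what the controls can deliver
  (gap > 0.25 rad/s), the same stop-and-rotate maneuver the game's
  controls afford. Without it, a near-miss at the target forces a 45 m
  loop and obstacle configurations with an obstacle near the approach
  corridor become uncompletable. `stop_threshold = Inf` restores
  forward-only control.

What the generator does *not* emulate: perceptual noise and reaction
delays, speed control, learning or fatigue across trials, and any
individual strategy beyond parameter variation. Passing tests on this
synthetic data therefore demonstrate that the pipeline's statistics
behave correctly and that the qualitative signature of interest — larger
within-group spread for the human-like population at every route type —
is reproduced under controlled conditions; they do not certify
quantitative agreement with any human dataset.

## Problem sizes and defaults used by the shipped checks

The test suite and the acceptance script run the comparison study at 10
agents per profile × 3 scenarios (one obstacle configuration crossed with
one start and three targets, covering all route types) × 6 repetitions,
and validate recovery on a 5-point in-bounds parameter grid with the
default optimizer budget. These sizes were chosen as the smallest designs
that exercise every route type, every pipeline stage, and all three
parameters' identifiability.

## Known limitations

* Differential evolution is stochastic-restart-free; a single seed's fit
  can sit in a local basin for pathological trajectories. The recovery
  harness quantifies this instead of assuming it away.
* The unstable symmetric equilibrium of the repeller (an obstacle exactly
  head-on exerts zero torque) is a property of the model itself; the
  generator's retry rule plays the role the game's restart rule played.
* Simulated agents do not leave the field, but nothing in continuous
  mode prevents an excursion past the walls mid-trajectory; the walls are
  observation features, not physical barriers, exactly as in raycast
  space.
* Fitted parameter scales depend on the radian convention; analyses
  comparing against degree-based reports of the same model family must
  convert.
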