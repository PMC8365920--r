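---
title: "gaitenv: model, reward system and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gaitenv: model, reward system and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitenv)
```

`gaitenv` is a desk-scale neuromechanical locomotion environment: a planar
seven-segment musculoskeletal walker driven by Hill-type muscles, a
target-velocity navigation task scored by a footstep-segmented reward, an
agent-facing step/reset interface, and reflex-style baseline controllers.
This vignette is the package's own account of the models inside it, the
parameters that matter, and the design decisions taken where the design was
genuinely open.

## The reward system

An episode runs for at most 2500 simulation steps of $\Delta t = 0.01$ s
(25 s).  The total reward decomposes exactly into three terms,

$$J = R_\mathrm{alive} + R_\mathrm{step} + R_\mathrm{target}
    = \sum_{i_\mathrm{sim}} b_\mathrm{alive}
    + \sum_{i_\mathrm{step}} \left( w_s b_s - w_v c_v - w_e c_e \right)
    + \sum_{i_\mathrm{target}} b_\mathrm{target},$$

with $b_\mathrm{alive} = 0.1$ per non-fallen simulation step, weights
$w_s = 10$, $w_v = 3$, $w_e = 1$, and $b_\mathrm{target} = 500$ for each of
the two targets.  Within each footstep,

* the **step bonus** $b_s = \sum \Delta t$ is the footstep duration, so the
  total step bonus over an episode depends only on the scored time, not on
  how it is partitioned into footsteps — many small steps and few large
  steps earn the same bonus;
* the **velocity cost**
  $c_v = \lVert \sum (v_\mathrm{pel} - v_\mathrm{tgt0}) \Delta t \rVert_2$
  penalises only the *average* velocity error over the footstep, so the
  instantaneous pelvis velocity may fluctuate freely within a step, as it
  does in human walking;
* the **effort cost** $c_e = \sum \sum_m A_m^2 \Delta t$ integrates squared
  muscle activation, a standard proxy for muscle fatigue.

A full-length episode with zero velocity and effort costs, continuous
stepping and both targets held therefore scores exactly
$250 + 250 + 1000 = 1500$; this decomposition is recomputed from scratch by
`scripts/acceptance.R` and asserted in the test suite.

**Footstep definition.** The reward is segmented by foot-contact events, but
what counts as a footstep is otherwise open.  Here a footstep closes when a
foot that has been airborne at least 50 ms regains contact (debouncing
contact chatter), with a forced closure after 5 s without any touchdown so
that standing phases are still scored, and the trailing partial step is
closed and scored at termination.  Without the forced closure, a standing
policy would accrue velocity and effort costs in an open step that is never
scored.

**$v_\mathrm{tgt0}$.** The commanded velocity entering the velocity cost is
the field vector evaluated at the pelvis position at each simulation step.

**Targets.** The commanded-velocity field points from the query position
toward the current target at the commanded speed (default 1.4 m/s, a typical
human walking speed), tapering linearly to zero inside the 0.3 m proximity
radius, which makes stopping and standing at the target optimal.  A target
is awarded (+500) once the pelvis has stayed within 0.3 m for a required
dwell drawn uniformly from 2–4 s; the dwell clock resets whenever the pelvis
leaves the radius.  Target locations are sampled from an annulus 2–6 m ahead
of the pelvis (the sampling law is not dictated by the task description;
uniform annulus sampling with a seeded RNG is this package's choice, and the
sagittal-plane walker samples targets straight ahead because it cannot
turn).

## The musculoskeletal model

The skeleton is a sagittal-plane kinematic tree of seven segments — a
combined head-arms-trunk-pelvis segment and thigh, shank and foot per leg —
with nine generalized coordinates (pelvis x, y, pitch; hip, knee, ankle per
leg).  Default anthropometry is a ~75 kg, ~1.80 m adult from standard
segment-parameter tables, stored entirely in the shipped configuration
(`inst/extdata/walker_default.yaml`).  Dynamics are assembled from point
Jacobians: the mass matrix as $M = \sum_i m_i J_{v,i}^\top J_{v,i} +
I_i J_{\omega,i}^\top J_{\omega,i}$, gravity and velocity-product forces
from the same Jacobians, and external point forces through $J^\top F$.  The
implementation is a generic planar-tree engine, so the pendulum, double
pendulum and projectile used as closed-form oracles in the tests run through
exactly the same code path as the walker.

**Planarisation.** The original task uses a 3D model with eight joints (two
hip degrees of freedom per side).  Building 3D contact dynamics from scratch
is out of proportion for a desk-scale reimplementation, and the reference
model has no internal yaw freedom anyway, so the core here is sagittal: six
revolute joints, with the frontal-plane hip muscles (HAB/HAD) retained as
effort-and-observation-only channels in the compatibility mode (below).

**Contact.** Each foot carries three contact spheres (heel, mid, toe).  The
normal force follows a Hunt–Crossley-style nonlinear spring-damper
$N = k\,d^{1.5}(1 + b\,\dot d)$, floored at zero (no adhesion), with
$k = 1.2 \times 10^6$ N/m$^{1.5}$ and $b = 1$ s/m; friction is smoothed
Coulomb, $F_t = -\mu N \tanh(v/v_s)$ with $\mu = 0.8$ and
$v_s = 0.05$ m/s.  These are standard choices for sphere-ground gait
contact; the stiffness was chosen so static standing penetration is a few
millimetres while remaining stable at the integration step.

**Integration.** Semi-implicit Euler with 10 sub-steps of 1 ms per 10 ms
control step.  This is first-order: the double-pendulum energy drift is
O(h) over a horizon and the momentum drift O(h²) per step, which the test
suite measures at finer sub-steps where the property, not the integrator
order, is under test.  For the stiff contact dynamics the semi-implicit
update is markedly more robust than explicit Euler at the same cost.

**Muscles.** Each leg is actuated by eleven Hill-type muscle-tendon units
(HAB, HAD, HFL, GLU, HAM, RF, VAS, BFSH, GAS, SOL, TA; HAM, RF and GAS are
biarticular).  The task description names the Hill structure but no
equations, so canonical forms are used and exposed in the configuration:

* excitation-to-activation: first-order dynamics with
  $\tau_\mathrm{act} = 15$ ms and $\tau_\mathrm{deact} = 50$ ms
  (conventional constants), integrated with the exact exponential update;
  excitations outside $[0,1]$ are clamped, since learning agents emit
  unconstrained outputs;
* active force-length: Gaussian bell $\exp(-((l-1)/0.30)^2)$ in normalized
  CE length;
* force-velocity: Hill hyperbola $(1+v)/(1-v/0.25)$ for shortening, with a
  C1-continuous saturating eccentric branch reaching a plateau of 1.5;
* passive force: quadratic $((l-1)/1)^2$ engaging at the optimal length.

The tendon is rigid by default (series element fixed at its slack length),
so the CE length is the MTU length minus slack.  Muscle paths are affine:
constant moment arms per muscle-joint pair, calibrated so every MTU sits at
its optimal CE length in the neutral standing pose.  Constant moment arms
overestimate CE excursion in deep flexion (real moment arms shrink and
tendons stretch), so the shipped optimal lengths are deliberately generous
and the passive curve gentle; without this, passive knee-extensor forces
make swing-leg flexion impossible and destabilise flight phases.  An
explicit consequence: this model is *not* claimed to match the original
platform's muscle kinematics numerically — the printed interface (22
actions, 97 + 242 observations) and the reward system are the reproduction
targets, not joint-level trajectories.

## Environment interface

Two modes:

* **compat-22** exposes the published interface: a 22-dimensional excitation
  action, a 97-dimensional body observation and a 242-dimensional target
  velocity map.  Only the totals are published; the layout here is the
  natural decomposition 9 pelvis entries + 2 legs × (3 ground-reaction
  components + 4 joint angles + 4 joint speeds + 11 muscles × (force,
  length, velocity)), right leg first, with frontal-plane entries as exact
  zeros.  HAB/HAD excitations drive activation dynamics, the effort cost and
  the observation, but have no mechanical action in the planar core.
* **planar-18** is the native sagittal interface: 18 excitations and an
  81-dimensional body vector, 9 + 2 × (2 GRF + contact flag + 3 angles +
  3 speeds + 9 muscles × 3).

The map flattens an 11 × 11 body-frame grid at 0.5 m spacing — forward
components first, then lateral; 11 × 11 × 2 = 242 is the unique natural
square-grid factorisation of the published total.  The centre cell equals
the $v_\mathrm{tgt0}$ used by the reward.

Episodes terminate at 2500 steps or when the pelvis drops below 0.6 m
(config-exposed; the task says only "not falling down").  The initial pose
is static standing with feet flat; an optional initial forward pelvis speed
supports gait initiation with the baseline controller.  Episodes are fully
deterministic given the seed and the action sequence; the environment keeps
a private RNG stream so its target sampling never perturbs the caller's RNG.

## Baseline controllers

`stand_policy()` holds the statically unstable standing pose with constant
low-level co-activation plus a postural reflex: an ankle servo around a
slightly dorsiflexed set-point with a forward-velocity term, a knee servo
through the vastii, and a combined trunk-pitch / hip-angle servo through
the hip muscles.  Pure co-activation cannot stabilise an inverted pendulum,
so feedback of some form is the minimal honest implementation.  The shipped
gains were selected by the package's own seeded evolution strategy with a
robustness-gated objective (candidates had to survive initial-speed
perturbations and a ±2% gain jitter), so the shipped behaviour is an
attractor rather than a single fragile trajectory; the same gate was used
for the reflex gait parameters.

`reflex_policy()` is a compact member of the classic reflex-control family:
a stance/swing finite-state machine per leg; stance combines the ankle
servo, positive force feedback of the plantarflexors and vastii, and a
trunk-balance contribution through the hip muscles; swing combines a hip
flexion drive with hamstring-stretch feedback, early-swing knee flexion,
late-swing deceleration and tibialis drive for foot clearance.  A long
double support triggers swing on the leg that has been in stance longer,
which breaks the standing deadlock and alternates stepping.  The control
laws read only observation entries.  The shipped parameters
(`inst/extdata/reflex_tuned.yaml`) come from the repository's own seeded
(μ, λ) evolution-strategy run; the shipped baseline is a property-level
demonstration — sustained stepping without falling — not a claim of
human-like gait.

`search_params()` is the derivative-free tuning hook: a seeded, rank-based
(μ, λ) evolution strategy with per-coordinate geometric step-size decay.
Non-finite objective values are assigned worst fitness so crashed rollouts
do not abort a search.

## The fixture generator and what it does (not) show

`fixture_spec()`/`generate_fixture()` construct trajectory logs with known
closed-form rewards and no physics: piecewise-constant pelvis velocity
profiles (optionally with exactly zero-mean within-step oscillation),
contact-flag sequences realising a footstep schedule, constant activation
profiles, and target-reach scenarios in which the pelvis follows the
commanded field exactly.  The expected rewards are computed by a literal
transcription of the reward formula over the spec's segments, deliberately
independent of the incremental ledger implementation under test; the suite
checks agreement at 1e-9 over randomised specs.

These fixtures emulate the *accounting* features of real episodes — footstep
segmentation, within-step velocity fluctuation, dwell bookkeeping — but not
their dynamics: a passing fixture suite validates the reward system, not the
realism of simulated gait.  Simulated-walker properties are tested
separately (determinism, finiteness, conservation laws, baseline stepping).

## Numerical choices and limitations

* Sub-millimetre initial contact penetration puts the model in approximate
  static equilibrium at reset.
* Degenerate muscle geometry (non-positive CE length) yields zero force and
  a flag rather than an error, signalling misconfiguration without killing
  a rollout.
* Zero-duration footsteps score zero with a warning flag.
* Joint limits are soft (300 N·m/rad springs engaged only outside the
  range, with damping applied only while violating).
* The scorer stops at the first fall, matching the live environment.
* Problem sizes in the test suite (episode lengths of tens of seconds,
  oracle integrations at 1e-5 s sub-steps, 60 randomised fixture specs)
  were chosen so the full suite exercises every property at comfortable
  margins on a single CPU.
* Known limitations: no 3D dynamics, no upper-body articulation, constant
  moment arms, rigid tendon by default, no metabolic energy model (effort
  is activation-squared only), and no claim of numerical equivalence with
  the original OpenSim-based platform beyond the printed interface and
  reward constants.

## Worked example

```{r example, eval = FALSE}
library(gaitenv)

# score the maximum-reward fixture
fx <- generate_fixture(fixture_spec())
res <- score_trajectory(fx$log)
res
#> Episode result (2500 simulation steps)
#>   J        = 1500.000000
#>   R_alive  = 250.000000
#>   R_step   = 250.000000
#>   R_target = 1000.000000
#>   footsteps: 32  (total duration 25.00 s)

# run the reflex baseline and inspect the decomposition
env <- walker_env(episode = episode_config(mode = "planar-18", seed = 3,
                                           forward_speed = 0.4))
out <- rollout(env, policy = "reflex",
               params = read_reflex_params(
                 system.file("extdata", "reflex_tuned.yaml",
                             package = "gaitenv")))
glance(out$result)
```
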