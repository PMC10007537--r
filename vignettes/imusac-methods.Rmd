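---
title: "Methods: inertia-constrained SAC for simulated gait"
author: "imusac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inertia-constrained SAC for simulated gait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imusac)
```

## The problem

Reinforcement-learning controllers for musculoskeletal walking models
trained purely on trajectory-optimization rewards (track a target
velocity with minimal muscle effort) tend to converge to gaits that
reach the goal but look nothing like human walking: crooked paths,
implausible posture, idiosyncratic cadence.  The idea implemented here
is to constrain training with a cheap reference recording — a single
pelvis-mounted IMU giving roll/pitch/yaw over a 5 m straight walk — by
adding, per simulation timestep, the negative absolute deviation
between the reference orientation and the simulated pelvis orientation
as three extra reward components.

## The reward model

The per-timestep reward is kept as a ten-component vector

```
r = [r_env, r_clp, r_vdp, r_pvb, r_dep, r_tab, r_entropy,
     r_imu_roll, r_imu_pitch, r_imu_yaw]
```

scalarized only where a scalar is needed, as `r_t = sum_i w_i r_{i,t}`.
The components:

* `r_env` — the trajectory-optimization composite: an alive bonus of
  0.1 per non-fallen timestep, a stepping reward `sum in_step_i dt`,
  minus a velocity cost (the *norm of the summed* in-step deviation
  `(v_vel - v_tgt) dt`, so oscillations around the target velocity
  cancel) and an effort cost `sum in_step_i sum_m A_m^2 dt`, with
  internal weights `w_step`, `w_vel`, `w_eff` (all default 1).
* `r_clp` — crossing-legs penalty `min(0, s)` where `s` is the scalar
  triple product `((r_left - r_pelvis) x (r_right - r_pelvis)) .
  (r_head - r_pelvis)`.  The source formulation of this term is
  ill-typed as printed (a min over a tuple of vectors); the triple
  product is the standard geometric score in this model lineage and
  reduces to the signed scalar the min requires.
* `r_vdp` — in-step velocity deviation penalty `-||v_body - v_tgt||`.
* `r_pvb` — pelvis velocity bonus `||v_body||`.
* `r_dep` — dense effort penalty `-||action||`.
* `r_tab` — target achievement bonus, piecewise in `||v_tgt||`:
  0 above 0.7 m/s, 0.1 on (0.5, 0.7], `1 - 3.5 ||v_tgt||^2` at or
  below 0.5 (so 1 exactly at a reached target).
* `r_entropy` — the SAC entropy bonus `alpha * (-log pi(a|s))`,
  togglable independently of the entropy term in the actor loss (both
  are on by default; the critic bootstrap deliberately excludes an
  additional entropy term so the bonus is not double-counted inside
  the value function).
* `r_imu_*` — `-|wrap(reference_axis - observed_axis)|` per axis, with
  differences wrapped to `(-pi, pi]` so residuals never jump by `2*pi`
  across the seam.  IMU channels are pelvis ZXY Euler angles in
  radians; the reference is resampled to the simulation timestep and
  aligned at episode start (no gait-phase warping).

### Weight calibration

The IMU weights are 1.  The per-component weights of the shaping terms
are not fixed by the method and had to be calibrated for the synthetic
walker: with every weight at 1 the dense effort penalty (about
−1.9 per step at walking excitation) dominates all locomotion bonuses,
and the true optimum of the scalar reward is to creep or fall — not
the behavior the reward is meant to induce.  The shipped defaults are
`r_pvb = 0.3` and `r_dep = 0.1` with all other components at 1, which
make steady walking at the cruise speed net-positive (~ +0.3 per step)
and put episode returns on the scale familiar from this literature
(maxima of order 10^2).  Both are exposed in the configuration.

## The learner

Soft Actor-Critic over a factorized Gaussian squashed into the muscle
excitation box `[0,1]^A` by `a = (tanh(u)+1)/2` with the standard
Jacobian correction of the log-density.  Departures from vanilla SAC:

* **One critic head per reward component.**  The critic outputs a
  vector `Q_i(s,a)`; each head regresses its own component's n-step
  target and the actor ascends the scalarized `sum_i w_i Q_i` (twin
  critics with element-wise minimum at bootstrap; a config flag
  restores the literal single-critic formulation).  Adding or removing
  a component is critic-head surgery: a removed head has its
  output-layer column and scalarization weight zeroed, an added head
  appends a freshly initialized column, and untouched heads are
  bit-identical before and after.
* **n-step targets with invertible value rescaling.**
  `y_i = h(sum_k gamma^k r_i + gamma^n h^{-1}(Q̄_i))` with
  `h(x) = sign(x)(sqrt(|x|+1)-1) + 1e-3 x`.  The full-scale
  configuration uses `n = 5`, `gamma = 0.99` and rescaling on.
* **Learned temperature** with target entropy `-dim(action)`.
* Networks follow the published full-scale shapes (four hidden layers,
  critic width 256, ELU policy / ReLU critic, Adam at 3e-5 / 1e-4,
  batch 256); all sizes are configuration entries.

Gradients are hand-derived and implemented in base R (dense layers,
backprop, Adam, global gradient-norm clipping at 10): no automatic
differentiation framework is involved, which keeps the package
dependency-free and makes every gradient testable against
finite-difference and descent checks.

## Segment replay

Experience is stored as fixed-length segments of `L = 10` consecutive
transitions that overlap by `L/2` and never cross episode boundaries
("overlap by half" is read as half the segment length — literal
half-timestep offsets are meaningless at fixed `dt`).  A short episode
tail is right-padded by repeating its final transition under a mask so
short episodes are not discarded.  Each segment carries a priority
`p = eta * max(delta) + (1 - eta) * mean(delta)` over its n-step
TD-error magnitudes (`eta = 0.9`); the TD magnitude is the absolute
*scalarized* error `|sum_i w_i TD_i|`, so a zero-weighted component
can never drive sampling.  Segments are drawn with probability
proportional to `p^alpha` and weighted by max-normalized importance
weights `(N P)^{-beta}`; both exponents ramp linearly from 0.1 to 0.9
over 3000 learner steps.  New segments enter at the maximum current
priority so each is visited at least once; eviction is FIFO at a
capacity of 250,000 transitions.  The data-collection worker count is
configurable; the shipped single-process mode is deterministic.

## Stage two: distillation

After stage one learns to walk, the policy and critic are distilled
into networks additionally conditioned on the local target-velocity
field (a 2 x 11 x 11 grid of 0.5 m cells centered on the agent, each
cell's vector pointing at the target: flattened length 242, giving
conditioned inputs 97 + 242 = 339 and 339 + 22 = 361 in the full-model
layout; hidden width 1024).  Training is offline on the saved stage-one
replay: the policy student minimizes `KL(student || teacher)`
(mode-seeking, exactly as the source writes it, although forward KL is
more common in distillation), the critic student a squared error to the
teacher's values, with the conditioning input perturbed per element by
zero-mean Gaussian noise.  The noise scale 0.1 is read as a *variance*
(the source does not say variance or standard deviation); it is
config-exposed.  Student and teacher draw their comparison actions
under a shared reparametrization noise, so an exact-copy student
provably incurs zero loss.  Teacher parameters are never touched.

## The synthetic walker

The full musculoskeletal physics environment is out of scope; the
shipped environment is a deliberately simple, fully deterministic
planar walker exposing the same interface contract
(`reset(seed) -> observation`; `step(action) -> observation,
kinematics, done`) and a documented 20-value observation / 6-muscle
action layout.  Its dynamics: first-order muscle activation
(`tau = 0.05 s`), pelvis speed relaxing toward `v_max * drive`
(`tau_v = 0.15 s` — responsive enough that an action has visible
consequences within the n-step credit-assignment horizon), heading rate
proportional to left/right activation imbalance, a posture proxy that
collapses in about 2 s without excitation (fall at `h < 0.5`), a gait
phase advancing at `drive / stride_period`, and phase-driven foot
contacts with double-support bands (a timestep is "in-step" when
exactly one foot is in contact).  Pelvis orientation oscillates with
the gait: roll once per stride, pitch twice (the double-peaked pelvic
tilt), yaw around the heading, with amplitudes (0.08 / 0.05 / 0.06
rad) in the range of human pelvic kinematics.

Two design choices matter for what the experiments can show:

* **A posture null-space.**  Pelvis tilt also depends on the
  ankle-versus-hip excitation mix, which leaves the mean drive — and
  hence every locomotion reward — unchanged.  This mirrors the premise
  that trajectory-optimization rewards underdetermine posture: without
  such a null direction the task reward alone pins the entire
  orientation and the IMU terms have nothing left to constrain.
* **Self-consistent reference conditions.**  The synthetic reference
  trace defaults to the walker's own gait at the task's cruise speed:
  stride period 1.28 s (= 1 s at full drive divided by the cruise
  drive 1.25/1.6), matching phase offsets, and harmonics (1, 2, 1).
  The "participant" walks at their comfortable cadence, which is also
  the task optimum, so the two reward groups do not pull against each
  other.

What the walker does *not* emulate: muscle force-length-velocity
mechanics, ground-reaction-force realism, 3D balance, or any
morphological detail.  Passing the shipped experiments therefore shows
that the training machinery expresses the IMU constraint as intended
on a system with the right interface and qualitative structure — not
that it reproduces human biomechanics.

## The reference generator

`generate_reference_imu()` emulates the undeposited pelvis recording:
per-axis sinusoid at the gait period (with per-axis harmonic counts),
plus linear drift and seeded Gaussian noise (sd 0.01 rad by default);
5 s at `dt = 0.01 s` gives 500 samples.  Real IMU recordings
additionally contain soft-tissue artifacts, sensor bias instability,
and stride-to-stride variability that the generator does not model.

## Study sizes and numerical choices

The package ships two configurations.  `default_config("full")`
carries the published hyperparameters (replay 250k, batch 256, four
256-wide hidden layers, 100 epochs) — the setting a GPU-scale run
would use.  `default_config("reduced")` is the desk-scale study used
by the tests, examples and acceptance script: 30 epochs of 3 episodes
(5 s horizon) plus 120 learner updates (batch 120 transitions = 12
segments), networks 32 x 32, `gamma = 0.95`, value rescaling off, and
Polyak `tau = 0.01`.  The last three reflect a scale effect: with
values of magnitude ~10^2, the compressive rescaling shrinks the
action-relevant part of the Q surface by more than an order of
magnitude, which a small critic trained for 3600 updates cannot
resolve; at desk scale plain targets with a shorter discount horizon
carry the signal.  Checkpoint selection follows the field's reporting
convention: the policy snapshot with the best smoothed return is kept
alongside the final agent.

Other numerical conventions: angle wrapping to `(-pi, pi]` before any
absolute difference; soft clamping of the policy log-std head to
[-5, 2] via a tanh rescaling (no dead gradient at the bounds); ZXY
Euler convention throughout with the gimbal degeneracy resolved by
folding the residual rotation into yaw; the target-velocity field
magnitude is the cruise speed 1.25 m/s tapering linearly to zero
inside 0.5 m of the target and exactly zero inside the 0.25 m stopping
radius, consistent with the `r_tab` thresholds.

## The ablation experiment

`imu_ablation_study()` trains two agents under identical configuration
and master seed — full reward vector versus the three IMU weights set
to zero — and compares (a) mean per-axis RMSE of a deterministic
rollout of each best checkpoint against the reference and (b) the
final smoothed return.  Because the two arms optimize differently
composed rewards, returns are compared after re-scalarizing the logged
per-component sums over the six shared task components at their
calibrated weights; comparing raw returns would conflate the extra
penalty terms with performance.  At the reduced scale the
IMU-constrained arm consistently achieves lower RMSE and no worse task
return; `scripts/acceptance.R` reruns this end to end.

## Known limitations

* Single-process training only; the parallel-worker count is a
  configuration hook, not an implementation.
* The random-target difficulty mode is a configuration hook only.
* Desk-scale training is noisy: single seeds can produce unstable
  runs in either arm; conclusions should always be drawn over matched
  seed pairs.
* The published full-physics RMSE magnitudes are not reproducible
  without the original simulator and recording; the package's RMSEs
  are on the synthetic walker's scale.
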