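---
title: "Movement-based control of a simulated transhumeral prosthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-based control of a simulated transhumeral prosthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridarm)
```

## The problem

A person with a transhumeral (above-elbow) amputation retains voluntary
control of the shoulder only. A prosthesis replacing the missing joints —
humeral rotation, elbow flexion-extension, forearm pronation-supination and
the two wrist rotations — must be driven somehow. Movement-based control
exploits the strong regularities of natural arm coordination: when the goal
of a reach is known, the distal joint angles can be predicted from the
proximal ones. The resulting *hybrid arm* reproduces the operator's two
shoulder angles directly and drives the five distal degrees of freedom (DoFs)
from a learned predictor, so the user simply "reaches" and the artificial
joints follow.

`hybridarm` implements this pipeline as a simulation: a 7-DoF arm model,
goal-aware distal-joint predictors, generation of the two target sets used to
train and test them, a deterministic synthetic-movement generator standing in
for recorded sessions, and closed-loop evaluation of the resulting controller
in a virtual pick-and-place task.

## The 7-DoF arm model

The arm is three rigid segments (upper arm, forearm, hand) linked by the
seven anatomical rotations `s_fe`, `s_aa`, `h_r`, `e_fe`, `f_ps`, `w_fe`,
`w_ru`, applied intrinsically in that proximal-to-distal order. The frame is
shoulder-centred: x anterior, y toward the subject's left, z up,
right-handed. In the zero posture the arm hangs along -z with the hand axis
pointing down. The rotation axes are: shoulder flexion about -y, abduction
about the rotated -x (so positive abduction is lateral for a right arm),
humeral rotation about the humeral axis, elbow flexion about the local -y,
pronation-supination about the forearm axis, wrist flexion about the local
-y and radial-ulnar deviation about the local +x. No published convention
exists for these signs, so the package fixes its own and keeps it fixed
everywhere; the three workspace filters below are coordinate-aligned with
this frame, which is the main reason for the choice.

A *hand location* is the 5-parameter description used throughout: the hand
centre (3 Cartesian coordinates, metres) plus the inclination and azimuth of
the hand's grasp axis relative to vertical. Cylindrical objects make the
rotation about the grasp axis irrelevant, so two orientation angles suffice.
When the axis is exactly vertical the azimuth is undefined and resolved to 0.

A left-sided arm is modelled as the mirror image of the right-sided chain:
`mirror_angles()` flips the four lateral/axial angles, `mirror_location()`
reflects across the medial plane, and forward kinematics commutes with both.

Humeral rotation deserves a note: on a real arm it cannot be tracked by a
sensor strapped to soft tissue, and is instead recovered from the triangle
formed by the shoulder, elbow and wrist centres
(`humeral_rotation_from_centers()`). That triangle degenerates when the arm
is straight — which is why the elbow's range of motion is artificially
limited to 85% of maximal extension everywhere in the pipeline: the
extension-side bound is pulled in by 15% of the observed elbow excursion
(`estimate_rom()`).

## Target sets

Two target sets mirror the two experimental phases:

* **Plausible targets** (`sample_plausible_targets()`, default 300) are drawn
  from a multivariate uniform distribution over the per-DoF ranges of motion,
  mapped through forward kinematics, and kept only if (1) the hand axis is
  within 80 degrees of vertical, (2) the centre is more than a third of the
  arm length in front of the frontal plane, and (3) at most two-thirds of the
  arm length below the shoulder plane. Inequalities (1) and (3) are
  non-strict and (2) is strict; the filters' source does not specify
  strictness, and the measure-zero boundary makes the choice immaterial in
  practice. Accepted targets are shuffled, half picking and half placing
  roles alternating.
* **Possible targets** (`gng_fit()` + `possible_targets()`, default 200) are
  obtained by fitting a Growing Neural Gas to the postures actually visited
  during an acquisition session (downsampled by 10; by 100 when pooling many
  donors), then mapping the resulting nodes through forward kinematics. They
  are guaranteed to be reachable by the movement repertoire that produced
  them. The ordering draws targets without replacement so that consecutive
  centres are at least 20 cm apart; the greedy draw restarts up to 1000
  times and fails loudly rather than relaxing the constraint.

The GNG reference only fixes the node budget (200), so the remaining
hyperparameters are the canonical ones (`lambda_insert = 100`,
`eps_b = 0.2`, `eps_n = 0.006`, `alpha = 0.5`, `beta = 0.995`,
`max_age = 50`), with Euclidean distance in radians over the 7-D posture
vector. Samples are presented in seeded random passes over the data;
insertion stops at the budget and the fit ends with the pass, so an
acquisition session of ordinary length (a few thousand downsampled postures)
reaches 200 nodes after a handful of passes. A budget unreachable within
`max_passes` raises an error instead of silently returning fewer nodes.

## The distal-joint predictor

The controller maps 7 inputs — the two proximal shoulder angles plus a
5-parameter goal location — to the five distal joint angles, with the
published stack: dense 256, dense 256, dropout 0.5, dense 64, linear 5
(ReLU hidden activations). Two ideas matter more than the architecture:

* **Hand location as target.** True target locations are piecewise-constant
  and highly clustered, which invites overfitting. Training instead treats
  every recorded posture as if it had just reached a target at its own hand
  location (`build_training_pairs()`), so the contextual input sweeps the
  workspace continuously.
* **Morphology remapping.** Donor recordings transfer to a new user by
  keeping the donors' joint-angle outputs but recomputing the contextual
  hand locations under the user's segment lengths
  (`build_generic_dataset()`), mirroring donors recorded on the opposite
  side first. The same postures on a longer arm put the hand elsewhere;
  remapping makes the inverse model consistent with the user's geometry.

Training minimises the mean-squared error by minibatch gradient descent,
with inputs and outputs z-scored per feature from the training set
(constants frozen into the model). Four numerical choices, each made after
measuring its effect on held-out recovery of the synthetic synergy, define
the default `training_config()`:

* **Optimizer: Adam, learning rate 1e-4, 30 epochs (rate divided by 10
  after epoch 22), batch 64.** The source protocol reports "learning rate
  1e-4" for own-data models without naming the optimizer; read as an Adam
  rate (the idiom of the Keras era it comes from) it trains this stack
  well, whereas plain SGD with momentum leaves 2-3x larger held-out error
  under the mandatory dropout layer and is much more seed-sensitive. The
  brief fine-tuning phase after the rate drop settles the
  dropout-perturbed weights before averaging. Classical SGD+momentum
  remains available (`optimizer = "sgd"`).
* **Orientation encoding.** The goal's two orientation angles are embedded
  as the three components of the unit hand axis before normalisation
  (`input_encoding = "axis"`). The raw spherical pair is discontinuous at
  the azimuth seam and unstable near the vertical pole (where every
  movement starts); the axis components are smooth everywhere. The
  documented 7-value pair format is unchanged — the embedding happens
  inside the model.
* **Tail averaging.** The weights visited during the final 8 epochs are
  averaged (Polyak-Ruppert); dropout injects gradient noise that otherwise
  leaves the final iterate at a random point of the converged region.
* **A small deep ensemble (`n_models = 3`).** Under the mandatory 0.5
  dropout, individual trainings of this stack occasionally converge with
  localised biases of several degrees that depend only on the
  initialisation draw; averaging the predictions of three independently
  initialised trainings removes these tails while leaving the stated
  architecture untouched. `n_models = 1` (used by both published presets)
  recovers the single-network protocol.

The published regimes are kept as named presets — `preset_own()` (30
epochs, learning rate 1e-4) and `preset_generic()` (10 epochs, learning
rate 1.59e-7, momentum 0.95, SGD) — as records of the protocol; their
learning rates were reported without the feature scaling they applied to,
so under this package's z-scoring the generic preset in particular barely
moves the weights. Inference is deterministic: dropout is inactive, and
predictions are clipped per-DoF to the training range, emulating
prosthesis joint limits.

## The synthetic movement generator

Real acquisition sessions are 90 Hz recordings of a person picking and
placing a bottle. The generator (`generate_session()`) emulates them with a
deterministic redundancy resolution: given a target, `synergy_ik()` places
the wrist one hand-length behind the target centre along the grasp axis,
computes elbow flexion by the law of cosines, fixes the elbow's position on
its circle by a constant swivel angle (0.3 rad, a natural slightly-lateral
elbow drop), aligns the forearm through humeral rotation, and aligns the
grasp axis with the two wrist angles while keeping pronation-supination at
zero. This last choice keeps every joint angle on a single continuous
branch across the entire workspace — no angle wraps — which makes the
proximal-to-distal relationship a smooth deterministic function of
(proximal, hand location) and therefore a valid ground truth for parameter
recovery.

Movements between successive reach postures are fifth-order minimum-jerk
interpolations in joint space (exact endpoints, zero endpoint velocity and
acceleration), sampled on the 1/rate grid: a nominal duration is quantized
to `round(duration * rate)` samples with the last sample exactly at the
goal. Gaussian angle jitter (default 0.5 degree per DoF per sample) stands
in for sensor and motor noise; the shoulder position carries a slow
sinusoidal drift (5 mm) plus small jitter, emulating a seated subject told
to keep their back against the chair. What the generator does **not**
emulate: muscle dynamics, reaction and dwell times, trunk compensation
strategies, tracker dropouts (except through `inject_artifacts()`), or the
variability of human redundancy resolution. Passing tests therefore show
the pipeline is correct and learnable under ideal coordination, not that
the controller would reach the same accuracy on human data.

## Closed-loop evaluation

`run_closed_loop_phase()` replays a simulated operator against a trained
model, one trial per target: the operator's shoulder angles follow a
minimum-jerk profile from the current posture toward the reference reach
posture for the goal; at every 90 Hz sample the model predicts the distal
angles from (current proximal, target location), the hybrid posture is
rendered by forward kinematics, and the trial succeeds at the first sample
whose hand location enters the target zone — position within `pos_tol` and
grasp axis within `ang_tol` (hard: 2 cm/5 degrees; relaxed: 4 cm/10
degrees). The simulated button has no press latency; an optional dwell is
off by default. After the ballistic reach the operator holds the final
shoulder posture; unlike a human participant it performs no visual
feedback correction, which makes the evaluation a strict open-loop test of
the predictor. Trials not validated within the time limit (presets: 5 s
acquisition-style, 10 s test-style) fail as timeouts. Movement time is the
time from target appearance to validation, reported for successful trials
only.

Data cleaning reproduces the two motion-capture filters: *freezing* (a
monitored position still — displacement under 1 micron per step — for at
least 0.5 s) and *jumping* (shoulder displacement above 0.01 m between
consecutive samples). For acquisition-style sessions both the shoulder and
the recomputed hand centre are monitored; for hybrid test phases only the
shoulder, since the hand is model-driven there.

The three phase metrics are the percentage of validated trials, the median
movement time of validated trials, and the shoulder *spread volume*: the
volume (dm^3) of the ellipsoid containing 90% of the shoulder positions,
computed by trimming the 10% of points farthest from the centroid in
Mahalanobis distance and fitting the minimum-volume enclosing ellipsoid
(Khachiyan's algorithm) to the rest. The construction is deterministic,
translation- and rotation-invariant, and scales volumes by the cube of an
isotropic scaling. Published human medians (success above 99%, movement
times around 1.2-1.4 s, spread volumes of 0.14-0.43 dm^3) depend on
participants and are not reproduction targets for the simulator.

## Numerical choices and degenerate inputs

* Angles are radians and positions metres everywhere in memory; files use
  degrees and metres.
* Rejection sampling of plausible targets fails after `10000 * n` draws;
  target sequencing after 1000 restarts; both report what rejected them.
* `synergy_ik()` rejects targets closer than 0.2 arm lengths or beyond the
  two-link workspace of the wrist; `generate_session()` names the offending
  target index.
* A rank-deficient shoulder cloud has zero spread volume (with a warning);
  fewer than 10 positions is an error.
* Exactly-vertical hand axes take azimuth 0; collinear joint centres make
  humeral rotation unrecoverable and raise an error.
* All randomised operations (sampling, GNG, sequencing, jitter, training)
  take explicit integer seeds and are bit-reproducible given one.

## Problem sizes used by the test-suite and acceptance script

The package's own evaluations run the default study conditions: 300
plausible targets, an acquisition session of ~35,000 samples at 90 Hz, a
200-node gas on the 10x-downsampled postures, and a test phase on the
possible targets. Parameter-recovery checks train on ~100,000 pairs from a
900-target session (the spatial density of reach endpoints, not the pair
count, is what limits interpolation accuracy between targets) and evaluate
on a 2,000-pair hold-out plus 100 closed-loop trials at the possible
targets — the same set the original test phases used, possible-by-
construction, whereas the plausible set deliberately includes
joint-extreme configurations that the source itself notes are often
infeasible in practice. These sizes keep a full run in minutes on one
core while matching the scale of a single-participant experiment.

## Known limitations

* The synthetic synergy is one fixed redundancy resolution; human inverse
  kinematics is variable and context-dependent, so real-data accuracy will
  be worse than parameter-recovery accuracy.
* The published training learning rates cannot be reproduced exactly
  without knowing the original feature scaling (see presets above).
* The simulated operator is open-loop: it cannot compensate predictor error
  with feedback corrections the way a human does, so simulated success
  rates lower-bound what a human operator would achieve with the same
  model.
* Predictions are not rate-limited or smoothed at target changes; a
  discontinuity at each target switch is inherent to goal-indexed
  prediction and is left visible.
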