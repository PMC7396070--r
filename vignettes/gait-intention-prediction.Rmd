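---
title: "Predicting lower-limb intention from interlimb gait synergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lower-limb intention from interlimb gait synergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitsynergy)
```

## The problem

Post-stroke hemiplegia weakens one side of the body; active gait
rehabilitation robots need an estimate of the *intended* lower-limb
trajectory to assist rather than drag the patient. During walking the limbs
are phase-coupled: each arm swings with the opposite leg. That interlimb
synergy means the recent trajectory of the *healthy* arm (and, if usable,
the healthy leg) carries enough information to predict the contralateral
hip and knee angle trajectories. `gaitsynergy` implements that prediction
pipeline end to end: markerless skeleton input, sagittal joint-angle
kinematics, a from-scratch peephole LSTM trained by backpropagation through
time, and per-joint, per-velocity RMSE evaluation.

## From skeletons to angles

Input is a stream of 3-D joint positions in camera space (metres; x right,
y up, z away from the sensor), nominally 30 frames/s, from the Kinect-style
25-joint skeletal model. Limb segments are proximal-minus-distal
differences of joint positions:

- upper arm: shoulder − elbow; forearm: elbow − wrist;
- thigh: hip − knee; shank: knee − ankle.

Each segment's angle is `theta = acos(u . r)` with `u` the unit segment and
`r` a unit reference direction, giving 8 channels (shoulder, elbow, hip,
knee × L, R), unsigned in [0, 180] degrees.

Two choices deserve explanation:

**Normalisation and clamping.** A raw dot product of metre-scaled vectors
lies outside arccos's domain, so both vectors are normalised first and the
dot product is clamped to [−1, 1]. This is the only reading under which the
angles are well-defined and land in the anatomical range.

**The reference direction.** The default `ref_mode = "vertical"` uses the
fixed upward vertical (0, 1, 0). Because segments point proximal-to-distal
*up* the limb, a limb hanging straight down then reads 0 degrees and the
angle is the familiar deviation-from-vertical flexion measure, invariant to
where the subject stands relative to the camera. The sensor-anchored
alternative (`"sensor-origin"`: the shoulder position minus the sensor
origin, normalised) is retained for comparison; it entangles the angle with
the subject's position in the room, which is why it is not the default.
Before the angle is taken, segment and reference are projected onto the
sagittal (y–z) plane (`project_sagittal = TRUE`), since flexion–extension
is a sagittal-plane quantity. Angles are unsigned — the arccos cannot
distinguish flexion from extension past the reference — and the package
documents rather than hides this.

Acquisition timestamps are only approximately uniform, so
`resample_uniform()` first places every sequence on an exact grid by linear
interpolation. Joints dropped by occlusion are gap-filled linearly up to
`max_gap = 5` frames (a sixth of a second at 30 fps); longer gaps mark the
affected channel invalid and those frames are excluded from training
windows rather than fabricated.

## The predictor

The core is a single-layer peephole LSTM, written from scratch in R with
64-bit arithmetic throughout:

```
i_t = sigmoid(Wxi x_t + Whi h_{t-1} + wci * c_{t-1} + bi)
f_t = sigmoid(Wxf x_t + Whf h_{t-1} + wcf * c_{t-1} + bf)
c_t = f_t * c_{t-1} + i_t * tanh(Wxc x_t + Whc h_{t-1} + bc)
o_t = sigmoid(Wxo x_t + Who h_{t-1} + wco * c_peep + bo)
h_t = o_t * tanh(c_t)
y_t = Wy h_t + by
```

The peephole weights `wci, wcf, wco` act elementwise (diagonally) on the
cell state, the established peephole contract. The output gate's peephole
argument `c_peep` is the *previous* cell state by default
(`peephole_output = "prev"`), matching the formulation this package
implements; the classical variant peeking at the current cell state is
available as `"current"`, and both variants are covered by the
finite-difference gradient check (`lstm_gradient_check()`), which verifies
every parameter group to a relative error below 1e-5.

Prediction is sequence-to-one: a window of 10 past frames of the input
channels predicts the target-joint angles one frame ahead (`lead = 1`;
longer horizons via the `lead` parameter). Two input configurations mirror
the two study conditions:

- `upper_only`: shoulder + elbow of one side → hip + knee of the opposite
  side;
- `upper_plus_lower`: shoulder + elbow + hip + knee of one side → hip +
  knee of the opposite side.

The target side is always contralateral to the input side, by construction
of `experiment_config()`.

## Training protocol and numerical choices

The protocol constants are a learning rate of 0.0005, a 10-frame window,
and at most 1000 training iterations. The remaining choices are this
package's own, and are worth recording:

- **Optimizer.** Adam (beta1 0.9, beta2 0.999) with global-norm gradient
  clipping at 5. At a fixed learning rate of 0.0005 and a 1000-iteration
  cap, plain SGD cannot move the weights far enough from a small random
  initialisation to fit anything: its per-step displacement is proportional
  to raw gradient magnitudes, which are tiny here. A "base learning rate"
  is also how adaptive-optimizer frameworks describe this constant. SGD
  remains available (`optimizer = "sgd"`) and shares the same
  gradient-checked BPTT.
- **Iteration = one minibatch gradient step** (batch 64), the sense in
  which deep-learning frameworks count iteration caps. Training stops
  early once 25-iteration loss-block means stop improving by 0.5 %
  relative for 3 consecutive blocks.
- **Initialisation.** Glorot-uniform weights, zero biases except the
  forget-gate bias at 1 (the standard trainability convention), zero
  peephole weights. A flat `uniform(-0.08, 0.08)` initialisation is
  available but leaves hidden activations so small that the readout cannot
  be fit within the iteration budget.
- **Hidden size 8** by default. The inputs are 2–4 band-limited,
  near-sinusoidal channels; raising the width to 16 changed held-out RMSE
  by less than 0.1 degrees in either direction on simulated sessions while
  doubling the run time of the 160-model experiment grid.
- **Standardisation.** Channels are standardised to zero mean and unit sd
  using statistics of the *training split only* (an sd floor of 1e-6
  degrees guards constant channels); the statistics travel with the model
  and predictions are de-standardised back to degrees, clamped to
  [0, 180] (`clamp_output`, default on).
- **Readout refit.** After the gradient phase, the linear readout
  `(Wy, by)` — the convex part of the model, and plumbing the recurrent
  formulation leaves unspecified — is refit in closed form by
  ridge-regularised least squares (lambda 1e-6) on the final-step hidden
  features of the training windows. This removes the residual first-order
  optimisation error in the output layer without touching the recurrent
  cell; on a noiseless lagged-copy problem it takes training RMSE from
  roughly half a degree to the numerical floor.
- **Split.** Temporal 80/20 per series. Sliding windows overlap by 9 of 10
  frames, so a shuffled split would leak almost every evaluation frame
  into training; windows straddling the boundary are dropped entirely
  (up to `window_len - 1` of them).
- **Divergence guard.** A non-finite loss aborts with the iteration index
  rather than returning silently broken weights.

`run_experiment()` trains one model per subject, velocity, contralateral
direction and configuration — both directions are run so all four target
joints (left/right hip and knee) are reported, as in the study's tables —
and aggregates held-out RMSE as mean ± sd across subjects. The per-velocity
`Total` row is the mean over the four joint cells' subject values. Models
are per-velocity (pooling velocities into one model is deliberately not
done: the report is defined around per-velocity cells, and cadence differs
across velocities).

## The gait simulator

The study's recordings are not redistributable, so the package ships a
simulator that generates skeleton streams with the statistical structure
the method relies on. Each angle channel follows a two-harmonic waveform

```
theta(t) = m + a1 sin(2 pi f t + phi) + a2 sin(4 pi f t + 2 phi)
```

with stride frequency `f(v) = 0.75 + 0.1 (v - 3)` Hz at `v` km/h
(literature-typical treadmill cadence; both constants are configuration,
not hard-coded). Construction enforces the interlimb structure: homologous
left/right channels are in exact antiphase, and each arm is in phase with
the contralateral leg (`arm_leg_phase = 0` by default — the synergy the
predictor exploits; no quantitative inter-limb phase value is available to
copy, so in-phase is the modelling choice, and it is configurable).
Channel means and amplitudes (e.g. hip 25 ± 12 ± 3 degrees) keep every
waveform inside [0, 180] with margin. `simulate_skeleton()` places
shoulder/hip anchors at fixed camera-space positions and swings each
segment in the sagittal plane so that the extracted angle equals the
template *exactly*; the round trip through `extract_angles()` reproduces
the template to < 1e-6 degrees and is the keystone integration test.

Noise enters as additive Gaussian angle jitter (default sd 0.5 degrees),
timestamp jitter (default 2 ms), and per-joint dropout. Cohorts perturb the
template per subject (amplitudes ±15 %, phases ±0.1 rad, seeded sub-draws);
10 subjects × 4 velocities gives the 40-session design of the emulated
study.

What the simulator does *not* model: stride-to-stride variability,
waveform families beyond two harmonics, pathological asymmetry, soft-tissue
and tracking artefacts correlated over time. Passing results on simulated
cohorts therefore demonstrate that the pipeline is correct and that the
method recovers a synergy of the assumed form — not that the printed
clinical accuracy transfers to real patients.

## Problem sizes used in the checks

The packaged experiment runs use 150 s sessions (4500 frames) in the
acceptance script and 60 s sessions in the test suite, both at 30 fps with
0.5-degree jitter and the full 10-subject × 4-velocity grid; the
seed-sweep monotonicity check (upper-plus-lower never worse than
upper-only on average) uses 5 seeds of 2-subject × 2-velocity × 30 s
cohorts. These sizes are the package's choice of a demonstration scale;
the bounds asserted (total held-out RMSE within 3 degrees in both
configurations, within 2 degrees for upper-plus-lower) do not change with
session length.

## Known limitations

- Angles are unsigned; flexion and extension to the same magnitude are
  indistinguishable, and signed conventions cannot be recovered from the
  arccos formulation.
- The `"sensor-origin"` reference mode depends on subject position; use it
  only for comparisons.
- Single-layer, single-direction LSTM; no multi-layer stacking, attention,
  or GPU path — the from-scratch core favours auditability, and the
  problem sizes here do not need more.
- Angular-displacement channels are extracted and can be fed to the model
  (`use_displacement`), but default off; on the simulator they add no
  information beyond the raw angles that generate them.
- Real-data ingestion is limited to the documented CSV/JSON-lines dialects;
  live sensor acquisition is out of scope.
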