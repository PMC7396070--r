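# gaitsynergy

Lower-limb intention prediction from interlimb gait synergy, for gait
rehabilitation research. During walking, each arm swings in phase with the
opposite leg; `gaitsynergy` exploits that coupling to predict the
contralateral hip and knee sagittal-plane angle trajectories from a short
window of upper-limb (optionally upper-plus-lower-limb) joint angles — the
signal an active rehabilitation robot needs in order to assist the impaired
side of a hemiplegic patient using motion of the healthy side.

The pipeline is:

1. **Skeleton I/O** — Kinect-style 25-joint position streams in a
   documented CSV or JSON-lines dialect (`read_skeleton()`,
   `write_skeleton()`), resampled onto an exact uniform grid
   (`resample_uniform()`).
2. **Kinematics** — limb-segment vectors are proximal-minus-distal joint
   differences (shoulder−elbow, elbow−wrist, hip−knee, knee−ankle); each
   joint angle is `theta = acos(u · r)` in degrees, with `u` the unit
   segment projected onto the sagittal plane and `r` the unit vertical
   reference (`extract_angles()`, `joint_angle()`), plus per-frame angular
   displacements (`angular_displacement()`).
3. **Peephole LSTM** — a from-scratch single-layer cell

   ```
   i_t = sigma(Wxi x_t + Whi h_{t-1} + wci * c_{t-1} + bi)
   f_t = sigma(Wxf x_t + Whf h_{t-1} + wcf * c_{t-1} + bf)
   c_t = f_t * c_{t-1} + i_t * tanh(Wxc x_t + Whc h_{t-1} + bc)
   o_t = sigma(Wxo x_t + Who h_{t-1} + wco * c_{t-1} + bo)
   h_t = o_t * tanh(c_t),   y_t = Wy h_t + by
   ```

   with exact backpropagation through time (`bptt_gradients()`) verified
   against central finite differences (`lstm_gradient_check()`).
4. **Experiment** — 10-frame sliding windows predict the next-frame
   contralateral hip/knee angles; models train per subject, velocity and
   direction at learning rate 0.0005 for at most 1000 iterations
   (`train_model()`, `run_experiment()`), and held-out RMSE is reported
   per joint and walking velocity as mean ± sd across subjects.
5. **Simulator** — since the original recordings are unavailable, a
   two-harmonic gait simulator with contralateral antiphase coupling,
   velocity-dependent cadence and sensor jitter generates skeleton cohorts
   with closed-form ground truth (`simulate_cohort()`,
   `simulate_skeleton()`).

See the methods vignette (`vignettes/gait-intention-prediction.Rmd`) for
the model assumptions, parameter defaults and design rationale.

## Worked example

```r
library(gaitsynergy)

# one simulated subject walking 60 s at 3 km/h, 0.5 deg sensor jitter
sk  <- simulate_skeleton(velocity_kmh = 3.0, duration_s = 60,
                         noise = noise_model(angle_jitter_sd = 0.5),
                         seed = 7)
ang <- extract_angles(resample_uniform(sk, 30))

# right shoulder + elbow windows -> next-frame left hip/knee angles
cfg <- experiment_config(input_mode = "upper_only", input_side = "R",
                         velocities = 3.0, seed = 7)
sp  <- split_train_eval(make_windows(ang, cfg), 0.8)
fit <- train_model(sp$train, cfg)
out <- predict_windows(fit, sp$eval)
round(c(hip_L  = rmse(out$pred[, "hip_L"],  sp$eval$targets[, "hip_L"]),
        knee_L = rmse(out$pred[, "knee_L"], sp$eval$targets[, "knee_L"])), 2)
#>  hip_L knee_L
#>   0.61   0.83
```

Held-out RMSE of 0.61 deg (hip) and 0.83 deg (knee) against a 0.5-deg
sensor-noise floor: the contralateral arm window predicts the leg
trajectory to well under a degree on simulated gait. On the full
10-subject, 4-velocity cohort the per-velocity totals stay within 3 deg
for the upper-limb-only configuration and within 2 deg when the
ipsilateral leg channels are added.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/gaitsynergy.R simulate --subjects 1 --velocities 3.0 \
    --duration 60 --seed 7 --out work/
Rscript inst/cli/gaitsynergy.R extract-angles --skeleton work/S01_v3.0.csv \
    --out work/angles.csv
Rscript inst/cli/gaitsynergy.R train --angles work/angles.csv \
    --out work/model.json
Rscript inst/cli/gaitsynergy.R evaluate --model work/model.json \
    --angles work/angles.csv --out work/eval.csv
```

Every command writes a JSON run manifest (config, seed, input digests,
outputs, wall time) next to its outputs.

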