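# Small fixtures shared across test files; everything is generated in code.

quiet_noise <- function() noise_model(0, 0, 0)

# A tiny hand-built skeleton sequence with all limb joints present.
tiny_skeleton <- function(n = 3, fps = 30) {
  joints <- required_joints()
  pos <- array(0, dim = c(n, length(joints), 3),
               dimnames = list(NULL, joints, c("x", "y", "z")))
  for (i in seq_len(n)) {
    for (j in seq_along(joints)) {
      pos[i, j, ] <- c(0.01 * j, 1 - 0.05 * j, 2.5 + 0.001 * i)
    }
  }
  skeleton_sequence((seq_len(n) - 1) / fps, pos, nominal_fps = fps,
                    subject_id = "T1", velocity_kmh = 3.0)
}

# Random-but-valid skeleton sequence for round-trip property tests.
random_skeleton <- function(n = 5, seed = 1, with_missing = FALSE) {
  set.seed(seed)
  joints <- c("ShoulderLeft", "ElbowLeft", "HipRight", "KneeRight")
  pos <- array(stats::rnorm(n * length(joints) * 3, 0, 1.5),
               dim = c(n, length(joints), 3),
               dimnames = list(NULL, joints, c("x", "y", "z")))
  if (with_missing) pos[2, 1, ] <- NA_real_
  t <- cumsum(stats::runif(n, 0.02, 0.05))
  skeleton_sequence(t, pos, nominal_fps = 30)
}

# Angle series whose target channel is an exactly lagged copy of an input
# channel: a problem the LSTM can solve to numerical-noise accuracy.
lagged_copy_series <- function(n = 900, lag = 1, fps = 30, seed = 4) {
  set.seed(seed)
  t <- (seq_len(n) - 1) / fps
  base <- 40 + 20 * sin(2 * pi * 0.8 * t) + 5 * sin(4 * pi * 0.8 * t + 1)
  ang <- matrix(30, n, 8, dimnames = list(NULL, angle_channels()))
  ang[, "shoulder_R"] <- base
  ang[, "elbow_R"] <- 40 + 10 * cos(2 * pi * 0.8 * t)
  ang[, "hip_L"] <- c(rep(base[1], lag), base[seq_len(n - lag)])
  ang[, "knee_L"] <- c(rep(base[1], lag), base[seq_len(n - lag)])
  joint_angle_series(t, ang, fps = fps, subject_id = "LAG",
                     velocity_kmh = 3.0)
}

fast_config <- function(...) {
  experiment_config(velocities = 3.0, ...)
}

# Small LSTM problem for gradient tests.
small_lstm_problem <- function(seed = 7, n_in = 3, H = 4, n_out = 2,
                               T_len = 6) {
  set.seed(seed)
  p <- lstm_init(n_in, H, n_out, seed = seed)
  p$wci <- stats::runif(H, -0.3, 0.3)
  p$wcf <- stats::runif(H, -0.3, 0.3)
  p$wco <- stats::runif(H, -0.3, 0.3)
  list(params = p,
       xs = matrix(stats::rnorm(n_in * T_len), n_in, T_len),
       targets = matrix(stats::rnorm(n_out * T_len), n_out, T_len))
}
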