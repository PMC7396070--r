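#' Gait waveform template
#'
#' Each of the 8 angle channels follows a two-harmonic waveform
#' `theta(t) = m + a1*sin(2*pi*f*t + phi) + a2*sin(4*pi*f*t + 2*phi)`, the
#' minimal family that reproduces the asymmetric flexion shape of real gait
#' while keeping closed-form ground truth. Stride frequency scales with
#' treadmill speed as `f(v) = f0 + k*(v - 3)`. Construction enforces the
#' interlimb structure the prediction method exploits: homologous left/right
#' channels are in antiphase (phase difference pi), and each arm swings with
#' the contralateral leg up to a configurable lead `arm_leg_phase`
#' (default 0, i.e. in phase).
#'
#' @param mean_deg,amp1_deg,amp2_deg Named vectors (names `shoulder`,
#'   `elbow`, `hip`, `knee`) of channel means and harmonic amplitudes in
#'   degrees.
#' @param phase_rad Within-cycle phase of each joint (radians) for the right
#'   side; the left side is shifted by pi.
#' @param f0_hz Stride frequency at 3.0 km/h.
#' @param k_hz_per_kmh Cadence-velocity slope.
#' @param arm_leg_phase Lead of the arm channels over the contralateral leg
#'   channels, radians.
#' @return A `gait_template` object.
#' @export
gait_template <- function(mean_deg = c(shoulder = 15, elbow = 25,
                                       hip = 25, knee = 30),
                          amp1_deg = c(shoulder = 8, elbow = 10,
                                       hip = 12, knee = 15),
                          amp2_deg = c(shoulder = 1.5, elbow = 2,
                                       hip = 3, knee = 5),
                          phase_rad = c(shoulder = 0, elbow = 0.5,
                                        hip = 0, knee = 0.7),
                          f0_hz = 0.75, k_hz_per_kmh = 0.1,
                          arm_leg_phase = 0) {
  joints <- c("shoulder", "elbow", "hip", "knee")
  for (v in list(mean_deg, amp1_deg, amp2_deg, phase_rad)) {
    if (!all(joints %in% names(v))) {
      stop("template vectors need entries for ", paste(joints, collapse = ", "),
           call. = FALSE)
    }
  }
  tpl <- structure(
    list(mean_deg = mean_deg[joints], amp1_deg = amp1_deg[joints],
         amp2_deg = amp2_deg[joints], phase_rad = phase_rad[joints],
         f0_hz = f0_hz, k_hz_per_kmh = k_hz_per_kmh,
         arm_leg_phase = arm_leg_phase),
    class = "gait_template")
  validate_gait_template(tpl)
}

validate_gait_template <- function(tpl) {
  lo <- tpl$mean_deg - abs(tpl$amp1_deg) - abs(tpl$amp2_deg)
  hi <- tpl$mean_deg + abs(tpl$amp1_deg) + abs(tpl$amp2_deg)
  if (any(lo < 0) || any(hi > 180)) {
    stop("template waveform leaves the [0, 180] degree range", call. = FALSE)
  }
  if (tpl$f0_hz <= 0) stop("stride frequency must be positive", call. = FALSE)
  tpl
}

stride_frequency <- function(tpl, velocity_kmh) {
  f <- tpl$f0_hz + tpl$k_hz_per_kmh * (velocity_kmh - 3.0)
  if (f <= 0) stop("cadence model gives non-positive frequency")
  f
}

# Phase of every channel. Right leg is the phase reference; left channels
# are antiphase; arms are in phase with the contralateral leg (+ lead).
channel_phases <- function(tpl) {
  ph <- tpl$phase_rad
  c(shoulder_R = ph[["shoulder"]] + pi + tpl$arm_leg_phase,
    elbow_R    = ph[["elbow"]] + pi + tpl$arm_leg_phase,
    hip_R      = ph[["hip"]],
    knee_R     = ph[["knee"]],
    shoulder_L = ph[["shoulder"]] + tpl$arm_leg_phase,
    elbow_L    = ph[["elbow"]] + tpl$arm_leg_phase,
    hip_L      = ph[["hip"]] + pi,
    knee_L     = ph[["knee"]] + pi)
}

#' Sensor-noise model
#'
#' @param angle_jitter_sd Additive angle noise, degrees (default 0.5).
#' @param timestamp_jitter_sd Frame-time jitter, seconds (default 0.002).
#' @param dropout_prob Per-joint per-frame missing probability (default 0).
#' @return A `noise_model` object.
#' @export
noise_model <- function(angle_jitter_sd = 0.5, timestamp_jitter_sd = 0.002,
                        dropout_prob = 0) {
  if (angle_jitter_sd < 0 || timestamp_jitter_sd < 0 || dropout_prob < 0 ||
      dropout_prob > 1) {
    stop("noise parameters must be non-negative (dropout_prob in [0, 1])")
  }
  structure(list(angle_jitter_sd = angle_jitter_sd,
                 timestamp_jitter_sd = timestamp_jitter_sd,
                 dropout_prob = dropout_prob),
            class = "noise_model")
}

template_angles <- function(tpl, velocity_kmh, time_s) {
  f <- stride_frequency(tpl, velocity_kmh)
  phases <- channel_phases(tpl)
  ang <- sapply(names(phases), function(ch) {
    j <- sub("_.*$", "", ch)
    tpl$mean_deg[[j]] +
      tpl$amp1_deg[[j]] * sin(2 * pi * f * time_s + phases[[ch]]) +
      tpl$amp2_deg[[j]] * sin(4 * pi * f * time_s + 2 * phases[[ch]])
  })
  ang <- matrix(ang, nrow = length(time_s),
                dimnames = list(NULL, names(phases)))
  ang[, angle_channels(), drop = FALSE]
}

#' Simulate joint-angle series for one walking session
#'
#' Returns both the noisy series (additive Gaussian angle jitter) and the
#' noiseless ground truth on the same exact grid.
#'
#' @param template A [gait_template()].
#' @param velocity_kmh Treadmill speed, km/h.
#' @param duration_s Session length, seconds (study protocol: 150 s).
#' @param fps Frame rate (study protocol: 30).
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param subject_id Identifier stamped on the output.
#' @return List with `noisy` and `truth`, both `joint_angle_series`.
#' @export
simulate_angles <- function(template = gait_template(), velocity_kmh = 3.0,
                            duration_s = 150, fps = 30,
                            noise = noise_model(), seed = 1,
                            subject_id = "sim") {
  if (duration_s <= 0 || fps <= 0) stop("duration and fps must be positive")
  validate_gait_template(template)
  n <- floor(duration_s * fps)
  time_s <- (seq_len(n) - 1L) / fps
  truth <- template_angles(template, velocity_kmh, time_s)
  set.seed(seed)
  noisy <- truth + matrix(stats::rnorm(length(truth), 0,
                                       noise$angle_jitter_sd),
                          nrow = n)
  noisy <- pmin(pmax(noisy, 0), 180)
  list(noisy = joint_angle_series(time_s, noisy, fps, subject_id,
                                  velocity_kmh),
       truth = joint_angle_series(time_s, truth, fps, subject_id,
                                  velocity_kmh))
}

#' Simulate a skeleton sequence for one walking session
#'
#' Inverse-kinematics fixture: shoulder and hip anchors sit at fixed camera-
#' space positions and each limb segment swings in the sagittal (y-z) plane
#' so that its angle against the upward vertical reference equals the
#' template waveform exactly. [extract_angles()] on a noiseless simulation
#' therefore recovers the template to numerical precision. Noise enters as
#' angle jitter before joint placement, timestamp jitter, and per-joint
#' dropout (`NA` coordinates).
#'
#' @inheritParams simulate_angles
#' @param segment_lengths Metres: upper arm, forearm, thigh, shank.
#' @return A `skeleton_sequence` with the 12 limb joints.
#' @export
simulate_skeleton <- function(template = gait_template(), velocity_kmh = 3.0,
                              duration_s = 150, fps = 30,
                              noise = noise_model(), seed = 1,
                              subject_id = "sim",
                              segment_lengths = c(upper_arm = 0.30,
                                                  forearm = 0.26,
                                                  thigh = 0.45,
                                                  shank = 0.43)) {
  if (duration_s <= 0 || fps <= 0) stop("duration and fps must be positive")
  validate_gait_template(template)
  n <- floor(duration_s * fps)
  grid <- (seq_len(n) - 1L) / fps
  set.seed(seed)
  time_s <- grid
  if (noise$timestamp_jitter_sd > 0) {
    time_s <- grid + stats::rnorm(n, 0, noise$timestamp_jitter_sd)
    time_s <- time_s - time_s[1]
    # enforce strict monotonicity without biasing the mean rate
    time_s <- cummax(time_s) + (seq_len(n) - 1L) * 1e-9
  }
  ang <- template_angles(template, velocity_kmh, grid)
  if (noise$angle_jitter_sd > 0) {
    ang <- ang + matrix(stats::rnorm(length(ang), 0, noise$angle_jitter_sd),
                        nrow = n)
    ang <- pmin(pmax(ang, 0), 180)
  }
  th <- ang * pi / 180
  anchors <- list(ShoulderLeft = c(-0.20, 1.40, 2.80),
                  ShoulderRight = c(0.20, 1.40, 2.80),
                  HipLeft = c(-0.10, 0.90, 2.80),
                  HipRight = c(0.10, 0.90, 2.80))
  joints <- c("ShoulderLeft", "ElbowLeft", "WristLeft",
              "ShoulderRight", "ElbowRight", "WristRight",
              "HipLeft", "KneeLeft", "AnkleLeft",
              "HipRight", "KneeRight", "AnkleRight")
  pos <- array(NA_real_, dim = c(n, length(joints), 3L),
               dimnames = list(NULL, joints, c("x", "y", "z")))
  # distal = proximal + L * (0, -cos(theta), sin(theta)): the
  # proximal-minus-distal segment then makes exactly theta with (0, 1, 0)
  place <- function(prox, theta, len) {
    sweep(cbind(0, -len * cos(theta), len * sin(theta)), 2, prox, `+`)
  }
  for (side in c("Left", "Right")) {
    sfx <- if (side == "Left") "L" else "R"
    sh <- anchors[[paste0("Shoulder", side)]]
    hp <- anchors[[paste0("Hip", side)]]
    pos[, paste0("Shoulder", side), ] <- matrix(sh, n, 3, byrow = TRUE)
    pos[, paste0("Hip", side), ] <- matrix(hp, n, 3, byrow = TRUE)
    elbow <- place(sh, th[, paste0("shoulder_", sfx)],
                   segment_lengths[["upper_arm"]])
    pos[, paste0("Elbow", side), ] <- elbow
    wrist <- elbow + cbind(0,
                           -segment_lengths[["forearm"]] *
                             cos(th[, paste0("elbow_", sfx)]),
                           segment_lengths[["forearm"]] *
                             sin(th[, paste0("elbow_", sfx)]))
    pos[, paste0("Wrist", side), ] <- wrist
    knee <- place(hp, th[, paste0("hip_", sfx)],
                  segment_lengths[["thigh"]])
    pos[, paste0("Knee", side), ] <- knee
    ankle <- knee + cbind(0,
                          -segment_lengths[["shank"]] *
                            cos(th[, paste0("knee_", sfx)]),
                          segment_lengths[["shank"]] *
                            sin(th[, paste0("knee_", sfx)]))
    pos[, paste0("Ankle", side), ] <- ankle
  }
  if (noise$dropout_prob > 0) {
    drop <- matrix(stats::runif(n * length(joints)) < noise$dropout_prob,
                   n, length(joints))
    for (j in seq_along(joints)) pos[drop[, j], j, ] <- NA_real_
  }
  seq <- skeleton_sequence(time_s, pos, nominal_fps = fps,
                           subject_id = subject_id,
                           velocity_kmh = velocity_kmh)
  # noiseless template angles on the exact grid, for oracle use
  attr(seq, "truth") <- joint_angle_series(
    grid, template_angles(template, velocity_kmh, grid), fps,
    subject_id, velocity_kmh)
  seq
}

#' Simulate a multi-subject, multi-velocity cohort
#'
#' Each subject gets an individually perturbed copy of the template
#' (amplitudes scaled by up to +/-15 %, phases shifted by up to +/-0.1 rad,
#' drawn from the subject's sub-seed) and walks one session per velocity,
#' mirroring the 10-subject, 4-velocity study design (10 x 4 = 40 sessions).
#'
#' @param n_subjects Number of simulated subjects.
#' @param velocities Velocities in km/h, one session each.
#' @param duration_s,fps,noise,template As in [simulate_skeleton()].
#' @param seed Master seed; subjects and sessions draw from sub-seeds.
#' @return List of `skeleton_sequence`, length `n_subjects *
#'   length(velocities)`, subjects labelled `S01, S02, ...`.
#' @export
simulate_cohort <- function(n_subjects = 10,
                            velocities = c(3.0, 3.5, 4.0, 4.5),
                            duration_s = 150, fps = 30,
                            noise = noise_model(), seed = 1,
                            template = gait_template()) {
  if (n_subjects < 1) stop("need at least one subject")
  out <- vector("list", n_subjects * length(velocities))
  k <- 0L
  for (s in seq_len(n_subjects)) {
    set.seed(seed + 7919L * s)
    tpl <- template
    scl1 <- 1 + stats::runif(4, -0.15, 0.15)
    scl2 <- 1 + stats::runif(4, -0.15, 0.15)
    dph <- stats::runif(4, -0.1, 0.1)
    tpl$amp1_deg <- tpl$amp1_deg * scl1
    tpl$amp2_deg <- tpl$amp2_deg * scl2
    tpl$phase_rad <- tpl$phase_rad + dph
    validate_gait_template(tpl)
    for (v in velocities) {
      k <- k + 1L
      out[[k]] <- simulate_skeleton(
        tpl, velocity_kmh = v, duration_s = duration_s, fps = fps,
        noise = noise, seed = seed + 7919L * s + round(100 * v),
        subject_id = sprintf("S%02d", s))
    }
  }
  out
}
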