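#' Segment vector between two joints
#'
#' The limb-segment vectors feeding the angle computation are plain
#' componentwise differences of joint positions, proximal minus distal:
#' shoulder-elbow, elbow-wrist, hip-knee, knee-ankle. No normalisation is
#' applied here.
#'
#' @param frame A single frame as returned by [skeleton_frame()], or any list
#'   with a `positions` joints-by-3 matrix.
#' @param tail,head Joint labels; the result is `position(tail) -
#'   position(head)`.
#' @return Numeric length-3 vector with attribute `zero_norm` flagging a
#'   degenerate (coincident-joint) segment.
#' @export
segment_vector <- function(frame, tail, head) {
  p <- frame$positions
  for (j in c(tail, head)) {
    if (!j %in% rownames(p) || anyNA(p[j, ])) {
      stop("joint missing from frame: ", j, call. = FALSE)
    }
  }
  v <- as.numeric(p[tail, ] - p[head, ])
  attr(v, "zero_norm") <- sqrt(sum(v^2)) == 0
  v
}

#' Reference vector for sagittal-plane angles
#'
#' `"vertical"` (the default) is the fixed upward vertical `(0, 1, 0)` in
#' camera space: a limb segment hanging straight down then reads 0 degrees,
#' and the angle is the familiar deviation-from-vertical flexion measure,
#' invariant to where the subject stands. `"sensor-origin"` reproduces the
#' sensor-anchored convention `v_s - v_o` (shoulder position minus sensor
#' origin, normalised), which depends on the subject's distance to the camera
#' and is kept for comparison.
#'
#' @param mode `"vertical"` or `"sensor-origin"`.
#' @param shoulder_pos For `"sensor-origin"`, the shoulder position (length-3)
#'   of the side being measured.
#' @return Unit length-3 numeric vector.
#' @export
reference_vector <- function(mode = c("vertical", "sensor-origin"),
                             shoulder_pos = NULL) {
  mode <- match.arg(mode)
  if (mode == "vertical") return(c(0, 1, 0))
  if (is.null(shoulder_pos) || anyNA(shoulder_pos)) {
    stop("sensor-origin reference needs the shoulder position", call. = FALSE)
  }
  v <- as.numeric(shoulder_pos)
  n <- sqrt(sum(v^2))
  if (n == 0) stop("shoulder at sensor origin: reference undefined")
  v / n
}

#' Angle between a segment and a reference direction
#'
#' Both vectors are normalised to unit length before the dot product (a raw
#' dot product of metre-scaled vectors would leave the arccos domain), the
#' dot is clamped to `[-1, 1]`, and the arccos is returned in degrees. The
#' result is unsigned, in `[0, 180]`.
#'
#' @param seg Segment vector (length 3), non-zero norm.
#' @param ref Reference vector (length 3), non-zero norm.
#' @return Angle in degrees.
#' @export
joint_angle <- function(seg, ref) {
  ns <- sqrt(sum(seg^2))
  nr <- sqrt(sum(ref^2))
  if (ns == 0 || nr == 0) stop("undefined angle: zero-norm vector")
  d <- sum(seg * ref) / (ns * nr)
  acos(min(1, max(-1, d))) * 180 / pi
}

#' Names of the 8 sagittal angle channels
#'
#' @return Character vector `shoulder/elbow/hip/knee x L/R`.
#' @export
angle_channels <- function() {
  c("shoulder_L", "elbow_L", "hip_L", "knee_L",
    "shoulder_R", "elbow_R", "hip_R", "knee_R")
}

# (proximal, distal) joint pair defining each angle channel
channel_segments <- function() {
  list(shoulder_L = c("ShoulderLeft", "ElbowLeft"),
       elbow_L    = c("ElbowLeft", "WristLeft"),
       hip_L      = c("HipLeft", "KneeLeft"),
       knee_L     = c("KneeLeft", "AnkleLeft"),
       shoulder_R = c("ShoulderRight", "ElbowRight"),
       elbow_R    = c("ElbowRight", "WristRight"),
       hip_R      = c("HipRight", "KneeRight"),
       knee_R     = c("KneeRight", "AnkleRight"))
}

#' Construct a joint-angle series
#'
#' Container for the 8 sagittal-plane angle channels (shoulder, elbow, hip,
#' knee on both sides) on a uniform time grid, all in degrees.
#'
#' @param time_s Uniform time grid, seconds.
#' @param angles `n x 8` matrix, columns named as [angle_channels()]. `NA`
#'   marks frames excluded as invalid.
#' @param fps Frame rate of the grid.
#' @param subject_id,velocity_kmh Metadata carried through from the skeleton.
#' @param displacement Optional `(n-1) x 8` matrix of per-frame angular
#'   displacements, degrees/frame.
#' @return An object of class `joint_angle_series`.
#' @export
joint_angle_series <- function(time_s, angles, fps = 30,
                               subject_id = NA_character_,
                               velocity_kmh = NA_real_,
                               displacement = NULL) {
  angles <- as.matrix(angles)
  if (nrow(angles) != length(time_s)) {
    stop("angles and time grid disagree in length", call. = FALSE)
  }
  if (is.null(colnames(angles))) colnames(angles) <- angle_channels()
  rng <- range(angles, na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 180 + 1e-9) {
    stop("angles must lie in [0, 180] degrees", call. = FALSE)
  }
  if (!is.null(displacement) && nrow(displacement) != nrow(angles) - 1L) {
    stop("displacement must have one row fewer than angles", call. = FALSE)
  }
  structure(list(time_s = as.numeric(time_s), angles = angles, fps = fps,
                 subject_id = subject_id, velocity_kmh = velocity_kmh,
                 displacement = displacement),
            class = "joint_angle_series")
}

#' @export
print.joint_angle_series <- function(x, ...) {
  cat(sprintf("joint_angle_series: %d frames x %d channels at %g fps\n",
              nrow(x$angles), ncol(x$angles), x$fps))
  if (!is.na(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  if (!is.na(x$velocity_kmh)) cat("  velocity:", x$velocity_kmh, "km/h\n")
  if (!is.null(x$displacement)) cat("  displacement channels attached\n")
  invisible(x)
}

# Linearly fill NA runs of length <= max_gap; longer runs stay NA.
gap_fill <- function(y, max_gap) {
  na <- is.na(y)
  if (!any(na)) return(y)
  r <- rle(na)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(!na)
  if (length(ok) < 2L) return(y)
  filled <- stats::approx(ok, y[ok], xout = seq_along(y), rule = 2)$y
  for (k in seq_along(r$lengths)) {
    if (r$values[k] && r$lengths[k] <= max_gap) {
      y[starts[k]:ends[k]] <- filled[starts[k]:ends[k]]
    }
  }
  y
}

#' Extract sagittal joint angles from a skeleton sequence
#'
#' Computes the 8 angle channels frame by frame: the shoulder angle from the
#' shoulder-elbow segment, elbow from elbow-wrist, hip from hip-knee, knee
#' from knee-ankle, each against the reference direction of
#' [reference_vector()]. With `project_sagittal = TRUE` (default) segment and
#' reference are first projected onto the sagittal (y-z) plane by zeroing the
#' mediolateral x component. Missing-joint gaps up to `max_gap` frames are
#' filled by linear interpolation of the coordinates; longer gaps leave the
#' affected channel `NA` on those frames.
#'
#' @param seq A uniform-rate `skeleton_sequence`.
#' @param ref_mode Reference convention, see [reference_vector()].
#' @param project_sagittal Project vectors onto the y-z plane first.
#' @param max_gap Longest missing-joint run (frames) to gap-fill.
#' @return A `joint_angle_series` with 8 channels.
#' @export
extract_angles <- function(seq, ref_mode = c("vertical", "sensor-origin"),
                           project_sagittal = TRUE, max_gap = 5) {
  ref_mode <- match.arg(ref_mode)
  validate_skeleton_sequence(seq)
  n <- n_frames(seq)
  joints <- dimnames(seq$positions)[[2]]
  segs <- channel_segments()
  need <- unique(unlist(segs))
  absent <- setdiff(need, joints)
  if (length(absent) > 0L) {
    stop("sequence lacks joints required for angles: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  pos <- seq$positions
  for (j in need) {
    for (ax in 1:3) pos[, j, ax] <- gap_fill(pos[, j, ax], max_gap)
  }
  ang <- matrix(NA_real_, n, length(segs),
                dimnames = list(NULL, names(segs)))
  for (ch in names(segs)) {
    a <- segs[[ch]][1]; b <- segs[[ch]][2]
    v <- pos[, a, , drop = TRUE] - pos[, b, , drop = TRUE]
    if (n == 1L) v <- matrix(v, 1L)
    if (ref_mode == "vertical") {
      r <- matrix(rep(c(0, 1, 0), each = n), n)
    } else {
      sh <- if (grepl("_L$", ch)) "ShoulderLeft" else "ShoulderRight"
      r <- pos[, sh, , drop = TRUE]
      if (n == 1L) r <- matrix(r, 1L)
    }
    if (project_sagittal) {
      v[, 1] <- 0
      r[, 1] <- 0
    }
    nv <- sqrt(rowSums(v^2))
    nr <- sqrt(rowSums(r^2))
    d <- rowSums(v * r) / (nv * nr)
    d[nv == 0 | nr == 0] <- NA_real_
    ang[, ch] <- acos(pmin(1, pmax(-1, d))) * 180 / pi
  }
  joint_angle_series(seq$time_s, ang, fps = seq$nominal_fps,
                     subject_id = seq$subject_id,
                     velocity_kmh = seq$velocity_kmh)
}

#' Per-frame angular displacement
#'
#' Attaches the first-difference channels `delta[t] = theta[t+1] - theta[t]`
#' (degrees per frame) to a series; these are the angular-velocity-style gait
#' features complementing the raw angles.
#'
#' @param series A `joint_angle_series` with at least 2 frames.
#' @return The series with its `displacement` field populated.
#' @export
angular_displacement <- function(series) {
  if (nrow(series$angles) < 2L) {
    stop("need at least 2 frames for angular displacement")
  }
  series$displacement <- diff(series$angles)
  series
}

#' Write a joint-angle series as tidy CSV
#'
#' Long format with columns `frame,time_s,joint,side,angle_deg` (plus
#' `displacement_deg` when displacement channels are attached).
#'
#' @param series A `joint_angle_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_angles <- function(series, path) {
  n <- nrow(series$angles)
  chans <- colnames(series$angles)
  side <- sub("^.*_", "", chans)
  joint <- sub("_.*$", "", chans)
  df <- data.frame(
    frame = rep(seq_len(n), times = length(chans)),
    time_s = rep(series$time_s, times = length(chans)),
    joint = rep(joint, each = n),
    side = rep(side, each = n),
    angle_deg = as.vector(series$angles))
  if (!is.null(series$displacement)) {
    df$displacement_deg <- as.vector(rbind(series$displacement,
                                           NA_real_))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tidy angle CSV back into a series
#'
#' @param path CSV written by [write_angles()].
#' @param fps,subject_id,velocity_kmh Metadata to attach.
#' @return A `joint_angle_series`.
#' @export
read_angles <- function(path, fps = 30, subject_id = NA_character_,
                        velocity_kmh = NA_real_) {
  df <- utils::read.csv(path)
  chans <- unique(paste0(df$joint, "_", df$side))
  n <- sum(df$joint == df$joint[1] & df$side == df$side[1])
  ang <- matrix(NA_real_, n, length(chans), dimnames = list(NULL, chans))
  for (ch in chans) {
    parts <- strsplit(ch, "_")[[1]]
    sel <- df$joint == parts[1] & df$side == parts[2]
    ang[, ch] <- df$angle_deg[sel]
  }
  time_s <- df$time_s[df$joint == df$joint[1] & df$side == df$side[1]]
  joint_angle_series(time_s, ang, fps = fps, subject_id = subject_id,
                     velocity_kmh = velocity_kmh)
}
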