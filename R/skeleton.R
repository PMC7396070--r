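#' Construct a skeleton sequence
#'
#' A `skeleton_sequence` holds per-frame 3-D joint positions in Kinect camera
#' space (metres; x right, y up, z away from the sensor) together with frame
#' timestamps. Missing joints (occlusion drop-outs) are `NA` coordinates.
#'
#' @param time_s Numeric vector of frame timestamps in seconds, strictly
#'   increasing.
#' @param positions Numeric array of dimension `n_frames x n_joints x 3` with
#'   joint labels as the second dimnames and `c("x","y","z")` as the third.
#'   `NA` marks a joint missing in that frame.
#' @param nominal_fps Nominal acquisition rate, frames per second.
#' @param subject_id Opaque subject identifier.
#' @param velocity_kmh Walking-speed label in km/h, or `NA` if unknown. Any
#'   positive value is accepted; the study protocol uses 3.0, 3.5, 4.0, 4.5.
#' @return An object of class `skeleton_sequence`.
#' @export
skeleton_sequence <- function(time_s, positions, nominal_fps = 30,
                              subject_id = NA_character_,
                              velocity_kmh = NA_real_) {
  if (!is.array(positions) || length(dim(positions)) != 3L ||
      dim(positions)[3] != 3L) {
    stop("positions must be an n_frames x n_joints x 3 array", call. = FALSE)
  }
  if (is.null(dimnames(positions)[[2]])) {
    stop("positions must carry joint labels as dimnames", call. = FALSE)
  }
  if (length(time_s) != dim(positions)[1]) {
    stop("length(time_s) must equal the number of frames", call. = FALSE)
  }
  dimnames(positions)[[3]] <- c("x", "y", "z")
  obj <- structure(
    list(time_s = as.numeric(time_s), positions = positions,
         nominal_fps = nominal_fps, subject_id = subject_id,
         velocity_kmh = velocity_kmh),
    class = "skeleton_sequence")
  validate_skeleton_sequence(obj)
}

validate_skeleton_sequence <- function(seq) {
  assert_known_joints(dimnames(seq$positions)[[2]])
  t <- seq$time_s
  if (length(t) == 0L) stop("sequence has no frames", call. = FALSE)
  bad <- which(diff(t) <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("timestamps must strictly increase; violation at frame %d",
                 bad[1] + 1L), call. = FALSE)
  }
  p <- seq$positions
  if (any(is.infinite(p) | is.nan(p))) {
    stop("coordinates must be finite or NA (missing)", call. = FALSE)
  }
  if (!is.na(seq$velocity_kmh) && seq$velocity_kmh <= 0) {
    stop("velocity_kmh must be positive", call. = FALSE)
  }
  seq
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  cat(sprintf(
    "skeleton_sequence: %d frames, %d joints, %.6g-%.6g s (nominal %g fps)\n",
    n_frames(x), dim(x$positions)[2], min(x$time_s), max(x$time_s),
    x$nominal_fps))
  if (!is.na(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  if (!is.na(x$velocity_kmh)) cat("  velocity:", x$velocity_kmh, "km/h\n")
  miss <- sum(is.na(x$positions)) / 3
  if (miss > 0) cat(sprintf("  missing joint observations: %d\n", miss))
  invisible(x)
}

#' Number of frames in a sequence
#' @param seq A `skeleton_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) length(seq$time_s)

#' Extract a single frame
#'
#' @param seq A `skeleton_sequence`.
#' @param i Frame index.
#' @return A list with `time_s` and `positions` (joints x 3 matrix).
#' @export
skeleton_frame <- function(seq, i) {
  stopifnot(i >= 1, i <= n_frames(seq))
  list(time_s = seq$time_s[i],
       positions = seq$positions[i, , , drop = TRUE])
}

skeleton_header <- function(joints) {
  c("timestamp", as.vector(t(outer(joints, c("_x", "_y", "_z"), paste0))))
}

#' Write a skeleton sequence to disk
#'
#' Two equivalent dialects are supported. `"csv"` is a flat table with header
#' `timestamp,<Joint>_x,<Joint>_y,<Joint>_z,...`; `"jsonl"` is JSON-lines with
#' one object per frame (`timestamp` plus the same keys). Coordinates are
#' written with enough digits that a read-back reproduces the sequence.
#'
#' @param seq A `skeleton_sequence`.
#' @param path Output file path.
#' @param dialect `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_skeleton <- function(seq, path, dialect = c("csv", "jsonl")) {
  dialect <- match.arg(dialect)
  validate_skeleton_sequence(seq)
  if (n_frames(seq) == 0L) stop("refusing to write an empty sequence")
  joints <- dimnames(seq$positions)[[2]]
  n <- n_frames(seq)
  flat <- matrix(aperm(seq$positions, c(1, 3, 2)), nrow = n)  # x,y,z per joint
  num <- function(v) sprintf("%.12g", v)
  if (dialect == "csv") {
    lines <- c(paste(skeleton_header(joints), collapse = ","),
               vapply(seq_len(n), function(i) {
                 paste(c(num(seq$time_s[i]), num(flat[i, ])), collapse = ",")
               }, character(1)))
    lines <- gsub("\\bNA\\b", "", lines)  # missing joints -> empty fields
    writeLines(lines, path)
  } else {
    keys <- skeleton_header(joints)[-1]
    lines <- vapply(seq_len(n), function(i) {
      rec <- c(list(timestamp = seq$time_s[i]),
               as.list(flat[i, ]))
      names(rec) <- c("timestamp", keys)
      jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null")
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a skeleton sequence from disk
#'
#' Parses the CSV or JSON-lines skeleton dialect written by
#' [write_skeleton()]. Unknown joint labels and non-monotone timestamps are
#' rejected with errors naming the offending column or row; empty fields are
#' taken as missing joints, never silently zeroed.
#'
#' @param path File to read.
#' @param dialect `"csv"` or `"jsonl"`.
#' @param nominal_fps,subject_id,velocity_kmh Metadata to attach (the file
#'   format itself stores only timestamps and coordinates).
#' @return A validated `skeleton_sequence`.
#' @export
read_skeleton <- function(path, dialect = c("csv", "jsonl"),
                          nominal_fps = 30, subject_id = NA_character_,
                          velocity_kmh = NA_real_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "csv") {
    lines <- readLines(path)
    if (length(lines) < 2L) stop("no data rows in ", path, call. = FALSE)
    header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
    if (header[1] != "timestamp") {
      stop("first column must be 'timestamp'", call. = FALSE)
    }
    coord_cols <- header[-1]
    parsed <- regmatches(coord_cols, regexec("^(.*)_([xyz])$", coord_cols))
    bad <- coord_cols[vapply(parsed, length, 1L) != 3L]
    if (length(bad) > 0L) {
      stop("malformed coordinate column(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    joints <- unique(vapply(parsed, `[`, character(1), 2L))
    assert_known_joints(joints)
    expect <- skeleton_header(joints)
    if (!identical(header, expect)) {
      stop("columns must be <Joint>_x,<Joint>_y,<Joint>_z groups in order",
           call. = FALSE)
    }
    nfield <- length(header)
    rows <- strsplit(lines[-1], ",", fixed = TRUE)
    vals <- matrix(NA_real_, nrow = length(rows), ncol = nfield)
    for (i in seq_along(rows)) {
      r <- rows[[i]]
      length(r) <- nfield  # short rows padded with NA then caught below
      if (length(rows[[i]]) != nfield) {
        stop(sprintf("malformed row at line %d: expected %d fields, got %d",
                     i + 1L, nfield, length(rows[[i]])), call. = FALSE)
      }
      v <- suppressWarnings(as.numeric(r))
      v[r == ""] <- NA_real_
      if (any(is.na(v) & r != "")) {
        stop(sprintf("malformed row at line %d: non-numeric field", i + 1L),
             call. = FALSE)
      }
      if (is.na(v[1])) {
        stop(sprintf("malformed row at line %d: missing timestamp", i + 1L),
             call. = FALSE)
      }
      vals[i, ] <- v
    }
    time_s <- vals[, 1]
    coords <- vals[, -1, drop = FALSE]
  } else {
    lines <- readLines(path)
    if (length(lines) == 0L) stop("no records in ", path, call. = FALSE)
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) {
                        stop(sprintf("malformed record at line %d: %s",
                                     i, conditionMessage(e)), call. = FALSE)
                      })
      if (is.null(rec$timestamp)) {
        stop(sprintf("malformed record at line %d: missing timestamp", i),
             call. = FALSE)
      }
      rec
    })
    keys <- setdiff(names(recs[[1]]), "timestamp")
    parsed <- regmatches(keys, regexec("^(.*)_([xyz])$", keys))
    bad <- keys[vapply(parsed, length, 1L) != 3L]
    if (length(bad) > 0L) {
      stop("malformed coordinate key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    joints <- unique(vapply(parsed, `[`, character(1), 2L))
    assert_known_joints(joints)
    keys <- skeleton_header(joints)[-1]
    time_s <- vapply(recs, function(r) as.numeric(r$timestamp), numeric(1))
    coords <- t(vapply(recs, function(r) {
      vapply(keys, function(k) {
        v <- r[[k]]
        if (is.null(v)) NA_real_ else as.numeric(v)
      }, numeric(1))
    }, numeric(length(keys))))
  }
  bad_t <- which(diff(time_s) <= 0)
  if (length(bad_t) > 0L) {
    stop(sprintf("timestamps must strictly increase; violation at row %d",
                 bad_t[1] + 1L), call. = FALSE)
  }
  positions <- aperm(array(coords,
                           dim = c(length(time_s), 3L, length(joints)),
                           dimnames = list(NULL, c("x", "y", "z"), joints)),
                     c(1, 3, 2))
  skeleton_sequence(time_s, positions, nominal_fps = nominal_fps,
                    subject_id = subject_id, velocity_kmh = velocity_kmh)
}

#' Resample a skeleton sequence onto an exact uniform grid
#'
#' Acquisition runs at only approximately the nominal frame rate; downstream
#' windowing assumes an exact grid. Output timestamps are
#' `t0, t0 + 1/fps, ...` spanning the input range; coordinates come from
#' per-axis linear interpolation between bracketing input frames. Missing
#' stretches in a channel stay `NA` on the grid points they cover.
#'
#' @param seq A `skeleton_sequence` with at least 2 frames.
#' @param target_fps Target rate in frames per second.
#' @return A `skeleton_sequence` on the uniform grid.
#' @export
resample_uniform <- function(seq, target_fps) {
  validate_skeleton_sequence(seq)
  if (n_frames(seq) < 2L) stop("need at least 2 frames to resample")
  if (target_fps <= 0) stop("target_fps must be positive")
  t_in <- seq$time_s
  t0 <- t_in[1]
  # grid may overshoot the last input timestamp by up to half a frame
  # (acquisition jitter); such points take the nearest-end value
  n_out <- floor((t_in[length(t_in)] - t0) * target_fps + 0.5) + 1L
  t_out <- t0 + (seq_len(n_out) - 1L) / target_fps
  joints <- dimnames(seq$positions)[[2]]
  out <- array(NA_real_, dim = c(n_out, length(joints), 3L),
               dimnames = list(NULL, joints, c("x", "y", "z")))
  for (j in seq_along(joints)) {
    for (ax in 1:3) {
      y <- seq$positions[, j, ax]
      ok <- !is.na(y)
      if (sum(ok) >= 2L) {
        out[, j, ax] <- stats::approx(t_in[ok], y[ok], xout = t_out,
                                      method = "linear", rule = 2)$y
        # grid points inside an NA gap stay NA rather than bridging it
        if (any(!ok)) {
          gap <- stats::approx(t_in, as.numeric(!ok), xout = t_out,
                               method = "linear", rule = 2)$y
          out[gap > 0 & !is.na(gap), j, ax] <- NA_real_
        }
      }
    }
  }
  skeleton_sequence(t_out, out, nominal_fps = target_fps,
                    subject_id = seq$subject_id,
                    velocity_kmh = seq$velocity_kmh)
}
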