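#' Kinect 25-joint vocabulary
#'
#' The joint identifiers of the Kinect v2 skeletal model. Skeleton files may
#' contain any subset of these; unknown labels are rejected at parse time.
#'
#' @return Character vector of the 25 joint labels.
#' @export
#' @examples
#' kinect_joint_names()
kinect_joint_names <- function() {
  c("SpineBase", "SpineMid", "Neck", "Head",
    "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
    "ShoulderRight", "ElbowRight", "WristRight", "HandRight",
    "HipLeft", "KneeLeft", "AnkleLeft", "FootLeft",
    "HipRight", "KneeRight", "AnkleRight", "FootRight",
    "SpineShoulder",
    "HandTipLeft", "ThumbLeft", "HandTipRight", "ThumbRight")
}

#' Joints required for sagittal angle computation
#'
#' The 12 limb joints (shoulder, elbow, wrist, hip, knee, ankle on both
#' sides) that the angle channels are built from.
#'
#' @return Character vector of joint labels.
#' @export
required_joints <- function() {
  c("ShoulderLeft", "ElbowLeft", "WristLeft",
    "ShoulderRight", "ElbowRight", "WristRight",
    "HipLeft", "KneeLeft", "AnkleLeft",
    "HipRight", "KneeRight", "AnkleRight")
}

assert_known_joints <- function(labels) {
  unknown <- setdiff(labels, kinect_joint_names())
  if (length(unknown) > 0L) {
    stop("unknown joint label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  invisible(labels)
}
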