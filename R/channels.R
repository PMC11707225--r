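# Canonical joint-angle channel layout used everywhere: 4 joints x 3
# planes, channel-major order (joint, then plane). Column c of a
# joint-angle tensor is channel c in this order; variable (c-1)*T + t of a
# PCA input row is time point t of channel c.

pk_joints <- c("ankle", "knee", "hip", "torso")
pk_planes <- c("sagittal", "frontal", "horizontal")

#' Canonical joint-angle channels
#'
#' The 12 channels (4 joints x 3 planes) in their fixed order: ankle,
#' knee, hip, torso; within each joint sagittal (X), frontal (Y),
#' horizontal (Z). Sign conventions for a right stance limb: dorsiflexion,
#' inversion and internal rotation positive at the ankle; flexion,
#' adduction and internal rotation positive proximally. Left-stance data
#' are mirrored to the same conventions.
#'
#' @return a data.frame with columns `channel`, `joint`, `plane`.
#' @export
angle_channels <- function() {
  data.frame(
    channel = paste(rep(pk_joints, each = 3L), rep(pk_planes, 4L), sep = "_"),
    joint = rep(pk_joints, each = 3L),
    plane = rep(pk_planes, 4L),
    stringsAsFactors = FALSE
  )
}

channel_names <- function() angle_channels()$channel

#' Joint-angle tensor
#'
#' Container for the 12 joint-angle series of one trial: a T x 12 matrix
#' (degrees) with the canonical channel columns of [angle_channels()] and
#' a sampling rate.
#'
#' @param angles T x 12 numeric matrix, degrees.
#' @param sample_rate sampling rate in Hz.
#' @return an object of class `joint_angle_tensor` (a matrix with
#'   attributes).
#' @export
joint_angle_tensor <- function(angles, sample_rate) {
  angles <- as.matrix(angles)
  if (ncol(angles) != 12L) stop("joint_angle_tensor requires 12 channels")
  if (!is.numeric(sample_rate) || sample_rate <= 0) stop("sample_rate must be > 0")
  colnames(angles) <- channel_names()
  structure(angles, sample_rate = sample_rate, class = "joint_angle_tensor")
}

# keep class/attributes when subsetting rows
ja_window <- function(angles, idx) {
  joint_angle_tensor(unclass(angles)[idx, , drop = FALSE],
                     attr(angles, "sample_rate"))
}
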