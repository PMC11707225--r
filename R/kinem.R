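# segment -> marker-cluster assignment is taken from the body template;
# angle extraction mirrors left-stance data onto right-stance conventions
# before fitting and restores the sign conventions afterwards.

#' Build rigid-body segment frames from marker clusters
#'
#' Least-squares rigid-body (orthogonal Procrustes) fit of each segment's
#' observed marker cluster to its template local coordinates, per sample.
#' The resulting rotations are exactly proper-orthogonal (via SVD with a
#' determinant correction); origins track each segment's joint centre.
#' Left-stance marker data are mirrored about the body midline before
#' fitting so both sides share the right-stance axis conventions
#' (X mediolateral flexion axis, Y anteroposterior, Z longitudinal).
#'
#' @param markers a [marker_set()].
#' @param template a [body_template()].
#' @param side stance side, `"right"` or `"left"`.
#' @return named list per segment: `rot` (T x 9 rotation series) and
#'   `origin` (T x 3, metres).
#' @export
build_segment_frames <- function(markers, template = body_template(),
                                 side = c("right", "left")) {
  side <- match.arg(side)
  stopifnot(inherits(markers, "marker_set"),
            inherits(template, "body_template"))
  pos <- unclass(markers)
  if (side == "left") {
    xcols <- seq(1L, ncol(pos), by = 3L)
    pos[, xcols] <- -pos[, xcols]
  }
  frames <- list()
  for (s in names(template$segments)) {
    seg <- template$segments[[s]]
    local <- seg$markers
    cols <- as.vector(vapply(rownames(local), function(l) {
      cn <- paste(l, c("X", "Y", "Z"), sep = "_")
      missing <- setdiff(cn, colnames(pos))
      if (length(missing)) stop("missing marker: ", l, " (segment ", s, ")")
      match(cn, colnames(pos))
    }, integer(3L)))
    obs <- pos[, cols, drop = FALSE]
    centred <- sweep(local, 2L, colMeans(local))
    if (qr(centred)$rank < 2L) stop("degenerate cluster in segment ", s)
    fit <- rigid_fit_cpp(obs, local)
    frames[[s]] <- list(rot = fit$rot, origin = fit$origin)
  }
  frames
}

#' X-Y-Z Euler joint angles between two segment frames
#'
#' Decomposes the relative rotation
#' `R_rel = t(R_proximal) %*% R_distal` per sample as
#' `Rx(alpha) %*% Ry(beta) %*% Rz(gamma)` and returns the unwrapped angle
#' series in degrees. Samples with `|beta| > 85` degrees are flagged as
#' gimbal-proximate.
#'
#' @param proximal,distal segment frames (lists with `rot` as T x 9
#'   series) from [build_segment_frames()].
#' @return T x 3 matrix of degrees (`alpha` sagittal, `beta` frontal,
#'   `gamma` horizontal) with attribute `gimbal`.
#' @export
joint_angles_xyz <- function(proximal, distal) {
  Rp <- if (is.list(proximal)) proximal$rot else proximal
  Rd <- if (is.list(distal)) distal$rot else distal
  if (nrow(Rp) != nrow(Rd)) stop("alignment error: frame lengths differ")
  euler_xyz(rot_compose(rot_transpose(Rp), Rd))
}

#' Extract the full joint-angle tensor from markers
#'
#' Runs [build_segment_frames()] and computes the four joints of the
#' chain: ankle (foot to shank), knee (shank to thigh), hip (thigh to
#' pelvis), torso (pelvis to torso). Left-stance trials are mirrored to
#' the right-stance frame before fitting, which maps every channel onto
#' its anatomical convention directly (no sign flips are needed: mirrored
#' inversion reads as inversion).
#'
#' @inheritParams build_segment_frames
#' @return a [joint_angle_tensor()].
#' @export
extract_joint_angles <- function(markers, template = body_template(),
                                 side = c("right", "left")) {
  side <- match.arg(side)
  frames <- build_segment_frames(markers, template, side)
  pairs <- list(ankle = c("foot", "shank"), knee = c("shank", "thigh"),
                hip = c("thigh", "pelvis"), torso = c("pelvis", "torso"))
  ang <- matrix(0, nrow(frames$foot$rot), 12L)
  for (j in seq_along(pairs)) {
    p <- pairs[[j]]
    ang[, (j - 1L) * 3L + 1:3] <-
      joint_angles_xyz(frames[[p[1]]], frames[[p[2]]])
  }
  joint_angle_tensor(ang, attr(markers, "sample_rate"))
}

# length-preserving first derivative: central differences in the
# interior, one-sided at the ends (exact for linear series)
deriv_central <- function(x, rate) {
  n <- length(x)
  if (n < 3L) stop("insufficient data: need >= 3 samples to differentiate")
  v <- numeric(n)
  v[1L] <- (x[2L] - x[1L]) * rate
  v[n] <- (x[n] - x[n - 1L]) * rate
  i <- 2:(n - 1L)
  v[i] <- (x[i + 1L] - x[i - 1L]) * rate / 2
  v
}

#' Joint angular velocity
#'
#' Time derivative of each unwrapped angle channel (degrees/s), central
#' differences in the interior and one-sided at the ends, length
#' preserving. `mode = "second"` differentiates twice, reproducing a
#' second-derivative reading of the angle series (an acceleration, kept
#' as an explicit switch; the first derivative is the default velocity
#' definition).
#'
#' @param angles a [joint_angle_tensor()] (or matrix with
#'   `sample_rate`).
#' @param mode `"first"` or `"second"` derivative.
#' @param sample_rate override when `angles` carries no rate.
#' @return matrix of the same shape, degrees/s (or degrees/s^2).
#' @export
angular_velocity <- function(angles, mode = c("first", "second"),
                             sample_rate = NULL) {
  mode <- match.arg(mode)
  rate <- attr(angles, "sample_rate") %||% sample_rate
  if (is.null(rate)) stop("sample_rate must be supplied")
  A <- unclass(angles)
  if (!is.matrix(A)) A <- matrix(A, ncol = 1L)
  if (nrow(A) < 3L) stop("insufficient data: need >= 3 samples")
  V <- apply(A, 2L, deriv_central, rate = rate)
  if (mode == "second") V <- apply(V, 2L, deriv_central, rate = rate)
  colnames(V) <- colnames(A)
  attr(V, "sample_rate") <- rate
  V
}

#' Discrete kinematic measures per channel
#'
#' Range of motion (maximum minus minimum angle) and root-mean-square
#' angular velocity over the analysed window.
#'
#' @param angles a [joint_angle_tensor()] (trimmed analysis window).
#' @param velocities optional velocity matrix; computed with
#'   [angular_velocity()] when omitted.
#' @return data.frame `channel, joint, plane, rom, rms_velocity`
#'   (degrees, degrees/s).
#' @export
discrete_measures <- function(angles, velocities = NULL) {
  A <- unclass(angles)
  if (is.null(velocities)) velocities <- angular_velocity(angles)
  ch <- angle_channels()
  data.frame(ch,
             rom = apply(A, 2L, function(x) max(x) - min(x)),
             rms_velocity = apply(unclass(velocities), 2L,
                                  function(v) sqrt(mean(v^2))),
             row.names = NULL)
}
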