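#' Five-segment stance-limb body template
#'
#' A stick-figure template for the stance-side kinematic chain (foot,
#' shank, thigh, pelvis, torso) with a rigid marker cluster per segment,
#' expressed in segment-local coordinates (metres). Each segment's origin
#' sits at its proximal-driving joint centre: ankle for foot and shank,
#' knee for thigh, hip for pelvis, pelvis top for torso. Lab axes:
#' X mediolateral (medial is negative for a right stance), Y
#' anteroposterior (forward positive), Z up.
#'
#' The foot cluster holds the four border markers used for the
#' time-to-boundary rectangle: calcaneus, first and fifth metatarsal
#' heads, first distal phalanx. Default dimensions are order-of-magnitude
#' anthropometrics (foot 0.25 x 0.10 m, shank and thigh 0.40 m, pelvis
#' 0.25 m, torso 0.50 m); all are overridable.
#'
#' @param foot_length,foot_width foot rectangle dimensions, metres.
#' @param ankle_height ankle joint centre height above the sole, metres.
#' @param shank_length,thigh_length,pelvis_height,torso_length segment
#'   lengths, metres.
#' @return an object of class `body_template`: per segment a marker
#'   matrix (rows = markers, columns X/Y/Z) and the offset of the next
#'   joint centre in the segment frame.
#' @export
body_template <- function(foot_length = 0.25, foot_width = 0.10,
                          ankle_height = 0.10, shank_length = 0.40,
                          thigh_length = 0.40, pelvis_height = 0.25,
                          torso_length = 0.50) {
  stopifnot(foot_length > 0, foot_width > 0, ankle_height > 0,
            shank_length > 0, thigh_length > 0, pelvis_height > 0,
            torso_length > 0)
  z0 <- -ankle_height
  heel <- -0.05                      # calcaneus marker behind the ankle
  mk <- function(...) {
    m <- rbind(...)
    colnames(m) <- c("X", "Y", "Z")
    m
  }
  segments <- list(
    foot = list(
      markers = mk(
        cal = c(0, heel, z0),
        toe = c(0, heel + foot_length, z0),
        mt1 = c(-foot_width / 2, heel + 0.18, z0),
        mt5 = c(foot_width / 2, heel + 0.18, z0)),
      next_joint = c(0, 0, 0)),
    shank = list(
      markers = mk(
        shank1 = c(0.05, 0.03, 0.08),
        shank2 = c(-0.05, 0.04, 0.14),
        shank3 = c(0.04, -0.05, 0.22),
        shank4 = c(-0.04, -0.04, 0.32)),
      next_joint = c(0, 0, shank_length)),
    thigh = list(
      markers = mk(
        thigh1 = c(0.06, 0.03, 0.08),
        thigh2 = c(-0.06, 0.04, 0.16),
        thigh3 = c(0.05, -0.06, 0.24),
        thigh4 = c(-0.05, -0.05, 0.34)),
      next_joint = c(0, 0, thigh_length)),
    pelvis = list(
      markers = mk(
        asis_l = c(-0.12, 0.08, 0.12),
        asis_r = c(0.12, 0.08, 0.12),
        psis_l = c(-0.06, -0.10, 0.14),
        psis_r = c(0.06, -0.10, 0.14)),
      next_joint = c(0, 0, pelvis_height)),
    torso = list(
      markers = mk(
        t8 = c(0, -0.07, 0.15),
        clav_l = c(-0.08, 0.04, 0.25),
        clav_r = c(0.08, 0.04, 0.25),
        c7 = c(0, 0.02, torso_length - 0.05)),
      next_joint = c(0, 0, torso_length))
  )
  for (s in names(segments)) {
    m <- segments[[s]]$markers
    if (nrow(m) < 3L) stop("degenerate template: segment ", s, " needs >= 3 markers")
    centred <- sweep(m, 2L, colMeans(m))
    if (qr(centred)$rank < 2L) {
      stop("degenerate template: collinear marker cluster in segment ", s)
    }
  }
  structure(list(segments = segments, ankle_height = ankle_height,
                 foot_length = foot_length, foot_width = foot_width),
            class = "body_template")
}

template_marker_names <- function(template) {
  unlist(lapply(template$segments, function(s) rownames(s$markers)),
         use.names = FALSE)
}

#' Forward kinematics: markers from joint angles
#'
#' Drives the five-segment template through the X-Y-Z Euler angle chain
#' ankle -> knee -> hip -> torso and returns the lab-frame marker
#' trajectories. The foot is fixed to the support surface (its mediolateral
#' position follows the platform displacement when supplied); each more
#' proximal segment is the rigid-body transform
#' `R_child = R_parent %*% Rxyz(joint angles)` about the chain's joint
#' centres. Exact (noise-free) unless `marker_noise_sd > 0`.
#'
#' For a left stance the whole body is mirrored about the midline plane
#' (lab X coordinates negated). Anatomical angle conventions survive the
#' mirror unchanged: rotations about the mediolateral axis (sagittal) are
#' reflection-invariant, and frontal/horizontal motions mirror onto their
#' anatomical counterparts (inversion to inversion, internal rotation to
#' internal rotation), so the same angle tensor describes either side.
#'
#' @param angles a [joint_angle_tensor()].
#' @param template a [body_template()].
#' @param platform_disp optional platform mediolateral displacement series
#'   (metres) of the same length as `angles`.
#' @param side `"right"` or `"left"` stance limb.
#' @param marker_noise_sd isotropic Gaussian marker noise SD in metres.
#' @return a `marker_set`: T x (3M) matrix with columns `<marker>_X/_Y/_Z`
#'   (metres) and attributes `labels` and `sample_rate`.
#' @export
forward_kinematics <- function(angles, template = body_template(),
                               platform_disp = NULL,
                               side = c("right", "left"),
                               marker_noise_sd = 0) {
  side <- match.arg(side)
  stopifnot(inherits(angles, "joint_angle_tensor"),
            inherits(template, "body_template"))
  n <- nrow(angles)
  if (!is.null(platform_disp) && length(platform_disp) != n) {
    stop("platform_disp length must match the angle series")
  }
  A <- unclass(angles)
  mirror <- side == "left"
  joints <- pk_joints
  rot <- vector("list", 5L)
  org <- vector("list", 5L)
  names(rot) <- names(org) <- names(template$segments)
  eye <- matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = n), n, 9L)
  rot$foot <- eye
  org$foot <- cbind(rep(0, n), 0, template$ankle_height)
  parent <- "foot"
  for (j in seq_along(joints)) {
    child <- names(template$segments)[j + 1L]
    cols <- (j - 1L) * 3L + 1:3
    Rj <- rot_xyz(A[, cols[1]], A[, cols[2]], A[, cols[3]])
    rot[[child]] <- rot_compose(rot[[parent]], Rj)
    off <- template$segments[[parent]]$next_joint
    org[[child]] <- org[[parent]] + rot_apply(rot[[parent]], off)
    parent <- child
  }
  labels <- template_marker_names(template)
  out <- matrix(0, n, 3L * length(labels))
  colnames(out) <- paste(rep(labels, each = 3L), c("X", "Y", "Z"), sep = "_")
  k <- 0L
  for (s in names(template$segments)) {
    m <- template$segments[[s]]$markers
    for (i in seq_len(nrow(m))) {
      pos <- org[[s]] + rot_apply(rot[[s]], m[i, ])
      out[, k + 1:3] <- pos
      k <- k + 3L
    }
  }
  if (mirror) {
    xcols <- seq(1L, ncol(out), by = 3L)
    out[, xcols] <- -out[, xcols]
  }
  if (!is.null(platform_disp)) {
    xcols <- seq(1L, ncol(out), by = 3L)
    out[, xcols] <- out[, xcols] + platform_disp
  }
  if (marker_noise_sd > 0) {
    out <- out + stats::rnorm(length(out), 0, marker_noise_sd)
  }
  marker_set(out, sample_rate = attr(angles, "sample_rate"))
}

#' Marker trajectory set
#'
#' @param positions T x (3M) matrix with columns `<marker>_X/_Y/_Z`,
#'   metres.
#' @param sample_rate sampling rate, Hz.
#' @return an object of class `marker_set`.
#' @export
marker_set <- function(positions, sample_rate) {
  positions <- as.matrix(positions)
  cn <- colnames(positions)
  if (is.null(cn) || ncol(positions) %% 3L != 0L) {
    stop("positions must have 3 named columns per marker")
  }
  labels <- unique(sub("_[XYZ]$", "", cn))
  if (length(labels) * 3L != ncol(positions)) {
    stop("positions columns must come in <marker>_X/_Y/_Z triples")
  }
  structure(positions, labels = labels, sample_rate = sample_rate,
            class = "marker_set")
}

#' Extract one marker's T x 3 trajectory
#' @param markers a `marker_set`.
#' @param label marker name.
#' @return T x 3 matrix (X, Y, Z), metres.
#' @export
marker_xyz <- function(markers, label) {
  cn <- paste(label, c("X", "Y", "Z"), sep = "_")
  missing <- setdiff(cn, colnames(markers))
  if (length(missing)) stop("missing marker: ", label)
  unclass(markers)[, cn, drop = FALSE]
}
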