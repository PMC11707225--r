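# Rotation series are stored as T x 9 matrices holding each sample's 3x3
# rotation in column-major order: r11,r21,r31,r12,r22,r32,r13,r23,r33.
# This layout keeps whole-trial composition and Euler decomposition
# vectorised over time.

#' Build an X-Y-Z Euler rotation series
#'
#' Composes `R = Rx(alpha) %*% Ry(beta) %*% Rz(gamma)` per sample, the
#' Cardan sequence used for joint angles throughout the package
#' (X = mediolateral/sagittal axis, Y = anteroposterior/frontal,
#' Z = longitudinal/horizontal).
#'
#' @param alpha,beta,gamma rotation angles in degrees (vectors of equal
#'   length, recycled scalars allowed).
#' @return a `length(alpha)` x 9 matrix of column-major rotation entries.
#' @export
rot_xyz <- function(alpha, beta, gamma) {
  n <- max(length(alpha), length(beta), length(gamma))
  a <- rep_len(alpha, n) * pi / 180
  b <- rep_len(beta, n) * pi / 180
  g <- rep_len(gamma, n) * pi / 180
  ca <- cos(a); sa <- sin(a)
  cb <- cos(b); sb <- sin(b)
  cg <- cos(g); sg <- sin(g)
  cbind(
    cb * cg,                    # r11
    ca * sg + sa * sb * cg,     # r21
    sa * sg - ca * sb * cg,     # r31
    -cb * sg,                   # r12
    ca * cg - sa * sb * sg,     # r22
    sa * cg + ca * sb * sg,     # r32
    sb,                         # r13
    -sa * cb,                   # r23
    ca * cb                     # r33
  )
}

#' Compose two rotation series
#'
#' Returns the per-sample product `A %*% B`.
#'
#' @param A,B T x 9 rotation series (see [rot_xyz()]).
#' @return a T x 9 rotation series.
#' @export
rot_compose <- function(A, B) {
  if (nrow(A) != nrow(B)) stop("rotation series lengths differ")
  C <- matrix(0, nrow(A), 9)
  for (i in 1:3) {
    for (j in 1:3) {
      acc <- 0
      for (k in 1:3) acc <- acc + A[, (k - 1L) * 3L + i] * B[, (j - 1L) * 3L + k]
      C[, (j - 1L) * 3L + i] <- acc
    }
  }
  C
}

#' Transpose a rotation series sample-wise
#' @param A a T x 9 rotation series.
#' @return the T x 9 series of transposed (inverse) rotations.
#' @export
rot_transpose <- function(A) {
  A[, c(1L, 4L, 7L, 2L, 5L, 8L, 3L, 6L, 9L), drop = FALSE]
}

#' Apply a rotation series to a fixed vector
#'
#' @param A a T x 9 rotation series.
#' @param v a length-3 vector (segment-local coordinates).
#' @return a T x 3 matrix of rotated vectors.
#' @export
rot_apply <- function(A, v) {
  stopifnot(length(v) == 3L)
  cbind(
    A[, 1] * v[1] + A[, 4] * v[2] + A[, 7] * v[3],
    A[, 2] * v[1] + A[, 5] * v[2] + A[, 8] * v[3],
    A[, 3] * v[1] + A[, 6] * v[2] + A[, 9] * v[3]
  )
}

#' Decompose a rotation series into X-Y-Z Euler angles
#'
#' Inverts [rot_xyz()]: `beta = asin(r13)`, `alpha = atan2(-r23, r33)`,
#' `gamma = atan2(-r12, r11)`. Angles are unwrapped over time so the series
#' is continuous. Samples with `|beta| > gimbal_deg` are flagged (near
#' gimbal lock the X/Z split is ill-conditioned).
#'
#' @param A a T x 9 rotation series.
#' @param gimbal_deg flag threshold on `|beta|` in degrees (default 85).
#' @return a T x 3 matrix of angles in degrees with columns `alpha`,
#'   `beta`, `gamma` and attribute `gimbal` (logical vector).
#' @export
euler_xyz <- function(A, gimbal_deg = 85) {
  r13 <- pmin(1, pmax(-1, A[, 7]))
  beta <- asin(r13)
  alpha <- atan2(-A[, 8], A[, 9])
  gamma <- atan2(-A[, 4], A[, 1])
  out <- cbind(alpha = unwrap_deg(alpha * 180 / pi),
               beta = unwrap_deg(beta * 180 / pi),
               gamma = unwrap_deg(gamma * 180 / pi))
  attr(out, "gimbal") <- abs(out[, 2]) > gimbal_deg
  out
}

#' Unwrap an angle series in degrees
#'
#' Removes jumps larger than 180 degrees between consecutive samples by
#' adding multiples of 360, so differentiation is well defined.
#'
#' @param x angle series in degrees.
#' @return unwrapped series.
#' @export
unwrap_deg <- function(x) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  corr <- cumsum(-360 * (d > 180) + 360 * (d < -180))
  x + c(0, corr)
}

# single 3x3 helpers used in tests and frame checks
rot_row_to_matrix <- function(row) matrix(row, 3L, 3L)
rot_matrix_to_row <- function(R) as.vector(R)
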