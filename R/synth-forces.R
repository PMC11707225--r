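# discretized mean-reverting (Ornstein-Uhlenbeck) sway process with
# stationary SD `sd` and reversion rate `theta`; `k` time-rescales the
# process (velocities scale by ~k, positions keep their spread)
ou_series <- function(n, dt, sd, theta, k = 1) {
  th <- theta * k
  if (th * dt >= 1) stop("invalid effect: velocity scale too large for the sample rate")
  sigma <- sd * sqrt(2 * th)
  e <- stats::rnorm(n, 0, sigma * sqrt(dt))
  as.numeric(stats::filter(e, 1 - th * dt, method = "recursive",
                           init = stats::rnorm(1, 0, sd)))
}

#' Generate a force-plate record with exactly consistent COP
#'
#' Simulates a trial's centre of pressure as a mean-reverting bounded
#' stochastic process inside the foot rectangle (plus a platform-entrained
#' mediolateral oscillation in the moving condition), then constructs
#' plate forces and moments such that the standard COP formula
#' (see [compute_cop()]) recovers the simulated COP exactly. The
#' group-by-condition velocity scale in `effects` time-rescales the sway
#' process, which is the mechanism planting time-to-boundary group
#' differences.
#'
#' Forces and moments are expressed at the plate origin with the plate
#' surface at the origin height (`d_z = 0`); the vertical force is body
#' weight with a small oscillation, and horizontal shear forces are small
#' sinusoids that do not enter the COP under `d_z = 0`.
#'
#' @param group `"CAI"` or `"HC"`.
#' @param condition `"static"` or `"moving"`.
#' @param effects a [group_effect_spec()].
#' @param foot_rect foot rectangle in the support-surface frame: list with
#'   `center` (x, y metres) and `half_ml`, `half_ap` (metres).
#' @param platform a [platform_spec()] (supplies duration and the
#'   entrainment frequency).
#' @param sample_rate force sampling rate, Hz (default 1000).
#' @param body_mass participant mass in kg (sets the vertical load).
#' @return list with `record` (data.frame `t,Fx,Fy,Fz,Mx,My,Mz`, N and
#'   N m, attribute `sample_rate`) and `cop` (T x 2 ground-truth COP,
#'   columns `x`, `y`, metres, support-surface frame).
#' @export
generate_cop_and_forces <- function(group = c("CAI", "HC"),
                                    condition = c("static", "moving"),
                                    effects = group_effect_spec(),
                                    foot_rect = default_foot_rect(),
                                    platform = platform_spec(),
                                    sample_rate = 1000,
                                    body_mass = 70) {
  group <- match.arg(group)
  condition <- match.arg(condition)
  stopifnot(inherits(effects, "group_effect_spec"),
            inherits(platform, "platform_spec"))
  if (is.null(foot_rect$center) || is.null(foot_rect$half_ml) ||
      is.null(foot_rect$half_ap)) {
    stop("foot_rect must provide center, half_ml, half_ap")
  }
  amp_ml <- effects$cop_entrain_amp * (condition == "moving")
  if (3 * effects$cop_sd + amp_ml > foot_rect$half_ml) {
    stop("invalid effect: COP spec exceeds the foot rectangle")
  }
  n <- round(platform$duration * sample_rate)
  dt <- 1 / sample_rate
  t <- (seq_len(n) - 1) * dt
  k <- effects$vel_scale[group, condition]
  x <- ou_series(n, dt, effects$cop_sd, effects$cop_theta, k)
  y <- ou_series(n, dt, effects$cop_sd * 1.5, effects$cop_theta, k)
  if (amp_ml > 0) {
    x <- x + amp_ml * sin(2 * pi * platform$frequency * t +
                            platform$phase_origin + pi)
  }
  # hard clip just inside the rectangle; exceedances are rare by design
  x <- pmin(pmax(x, -0.95 * foot_rect$half_ml), 0.95 * foot_rect$half_ml)
  y <- pmin(pmax(y, -0.95 * foot_rect$half_ap), 0.95 * foot_rect$half_ap)
  cop <- cbind(x = foot_rect$center[1] + x, y = foot_rect$center[2] + y)
  fz <- -body_mass * 9.81 * (1 + 0.01 * sin(2 * pi * 0.4 * t))
  fx <- 2 * sin(2 * pi * 1.1 * t)
  fy <- 2 * cos(2 * pi * 0.9 * t)
  # invert the COP formula (d_z = 0): COPx = -My/Fz, COPy = Mx/Fz
  my <- -cop[, 1] * fz
  mx <- cop[, 2] * fz
  record <- data.frame(t = t, Fx = fx, Fy = fy, Fz = fz,
                       Mx = mx, My = my, Mz = 0)
  attr(record, "sample_rate") <- sample_rate
  list(record = record, cop = cop)
}

#' Default foot rectangle matching the body template
#'
#' Axis-aligned rectangle of the template's four foot-border markers in
#' the support-surface frame (0.25 m long, 0.10 m wide, centred on the
#' foot).
#' @param template a [body_template()].
#' @return list with `center`, `half_ml`, `half_ap`.
#' @export
default_foot_rect <- function(template = body_template()) {
  m <- template$segments$foot$markers
  list(center = c(mean(range(m[, "X"])), mean(range(m[, "Y"]))),
       half_ml = diff(range(m[, "X"])) / 2,
       half_ap = diff(range(m[, "Y"])) / 2)
}
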