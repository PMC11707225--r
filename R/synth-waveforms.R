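# Reference single-leg stance posture (degrees) shared by both groups.
base_posture <- function() {
  c(ankle_sagittal = 5, ankle_frontal = 2, ankle_horizontal = 1,
    knee_sagittal = 10, knee_frontal = 0, knee_horizontal = 0,
    hip_sagittal = 8, hip_frontal = 2, hip_horizontal = 0,
    torso_sagittal = 5, torso_frontal = 0, torso_horizontal = 0)
}

# fixed per-channel phase lags of the entrained response (radians);
# distal channels respond earlier than proximal ones
entrain_phase <- function() {
  stats::setNames(rep(c(0, 0.25, 0.5, 0.7), each = 3L), channel_names())
}

# stationary AR(1)-coloured Gaussian noise with the requested SD
colored_noise <- function(n, sd, phi) {
  if (sd == 0) return(numeric(n))
  if (phi == 0) return(stats::rnorm(n, 0, sd))
  e <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(e, phi, method = "recursive",
                           init = stats::rnorm(1, 0, sd)))
}

# draw the between-participant quantities once per synthetic participant
draw_participant <- function(group, effects) {
  ch <- channel_names()
  baseline <- base_posture() +
    effects$offsets * (group == "CAI") +
    stats::rnorm(12L, 0, effects$offset_sd)
  names(baseline) <- ch
  list(baseline = baseline,
       phase = stats::rnorm(1L, 0, 0.3),
       amp_scale = exp(stats::rnorm(1L, 0, 0.15)))
}

#' Generate one trial of synthetic joint-angle waveforms
#'
#' Each channel is a participant baseline plus, in the moving condition, a
#' sinusoid entrained at the platform frequency, plus AR(1)-coloured
#' Gaussian noise. The expected CAI-minus-HC contrast of a channel equals
#' the signed offset in the effect specification; the static condition
#' contains no component at the platform frequency.
#'
#' @param group `"CAI"` or `"HC"`.
#' @param condition `"static"` or `"moving"`.
#' @param effects a [group_effect_spec()].
#' @param platform a [platform_spec()]; supplies the trial length, sample
#'   rate and entrainment frequency.
#' @param participant optional participant draw (list with `baseline`,
#'   `phase`, `amp_scale`) as produced internally by the cohort generator;
#'   a fresh participant is drawn when omitted.
#' @return a [joint_angle_tensor()] of dimension
#'   `round(duration * sample_rate)` x 12.
#' @export
generate_joint_waveforms <- function(group = c("CAI", "HC"),
                                     condition = c("static", "moving"),
                                     effects = group_effect_spec(),
                                     platform = platform_spec(),
                                     participant = NULL) {
  group <- match.arg(group)
  condition <- match.arg(condition)
  stopifnot(inherits(effects, "group_effect_spec"),
            inherits(platform, "platform_spec"))
  if (is.null(participant)) participant <- draw_participant(group, effects)
  n <- round(platform$duration * platform$sample_rate)
  t <- (seq_len(n) - 1) / platform$sample_rate
  ch <- channel_names()
  ang <- matrix(0, n, 12L)
  phases <- entrain_phase()
  for (c_i in seq_len(12L)) {
    level <- participant$baseline[c_i] +
      stats::rnorm(1L, 0, effects$trial_sd)
    x <- rep(level, n)
    if (condition == "moving") {
      amp <- effects$entrain_amp[c_i] * participant$amp_scale
      if (amp != 0) {
        x <- x + amp * sin(2 * pi * platform$frequency * t +
                             platform$phase_origin +
                             phases[ch[c_i]] + participant$phase)
      }
    }
    x <- x + colored_noise(n, effects$noise_sd, effects$ar_coef)
    ang[, c_i] <- x
  }
  joint_angle_tensor(ang, platform$sample_rate)
}
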