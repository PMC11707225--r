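#' Generate a synthetic balance-study cohort
#'
#' Builds a complete synthetic data set for the single-leg balance
#' paradigm: `n_per_group` participants per group (CAI, HC), each
#' performing 3 trials per condition on a static and/or moving platform,
#' with per-trial platform displacement, ground-truth joint-angle
#' waveforms, forward-kinematic marker trajectories, and force-plate
#' records whose centre of pressure is exactly recoverable. The generation
#' is deterministic given `seed` (the caller's random-number state is left
#' untouched).
#'
#' @param n_per_group participants per group (>= 2); the study design uses
#'   23.
#' @param conditions subset of `c("static", "moving")`.
#' @param effects a [group_effect_spec()].
#' @param platform a [platform_spec()].
#' @param template a [body_template()].
#' @param seed integer seed.
#' @param n_trials trials per participant-condition (default 3).
#' @param sides stance-side assignment: `"right"`, `"left"`, or `"mixed"`
#'   (alternating).
#' @param include_markers,include_forces generate marker trajectories /
#'   force-plate records (disable to save memory when only ground-truth
#'   angles are needed).
#' @param marker_noise_sd marker noise SD in metres (default 0.5 mm).
#' @param force_rate force-plate sampling rate, Hz.
#' @return an object of class `synthetic_cohort`: list with `manifest`
#'   (data.frame `participant,group,condition,side,trial,trial_id`),
#'   `trials` (named list per trial: `platform`, `angles` ground truth,
#'   `markers`, `forces`, `cop` ground truth), and the generating specs.
#' @export
generate_cohort <- function(n_per_group = 23,
                            conditions = c("static", "moving"),
                            effects = group_effect_spec(),
                            platform = platform_spec(),
                            template = body_template(),
                            seed = 1L,
                            n_trials = 3L,
                            sides = c("right", "left", "mixed"),
                            include_markers = TRUE,
                            include_forces = TRUE,
                            marker_noise_sd = 5e-4,
                            force_rate = 1000) {
  if (n_per_group < 2) stop("insufficient cohort: n_per_group must be >= 2")
  conditions <- match.arg(conditions, several.ok = TRUE)
  sides <- match.arg(sides)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  n_total <- 2L * n_per_group
  pid <- sprintf("S%02d", seq_len(n_total))
  group <- rep(c("CAI", "HC"), each = n_per_group)
  side <- switch(sides,
                 right = rep("right", n_total),
                 left = rep("left", n_total),
                 mixed = rep(c("right", "left"), length.out = n_total))
  foot_rect <- default_foot_rect(template)
  platform_disp <- generate_platform_trajectory(platform)

  manifest <- expand.grid(trial = seq_len(n_trials), condition = conditions,
                          idx = seq_len(n_total), stringsAsFactors = FALSE)
  manifest <- data.frame(participant = pid[manifest$idx],
                         group = group[manifest$idx],
                         condition = manifest$condition,
                         side = side[manifest$idx],
                         trial = manifest$trial,
                         stringsAsFactors = FALSE)
  manifest$trial_id <- sprintf("%s_%s_t%d", manifest$participant,
                               manifest$condition, manifest$trial)
  # order rows participant-major for readability
  manifest <- manifest[order(match(manifest$participant, pid),
                             match(manifest$condition, conditions),
                             manifest$trial), ]
  rownames(manifest) <- NULL

  trials <- vector("list", nrow(manifest))
  names(trials) <- manifest$trial_id
  for (i in seq_len(n_total)) {
    part <- draw_participant(group[i], effects)
    for (cond in conditions) {
      disp <- if (cond == "moving") platform_disp else
        rep(0, length(platform_disp))
      for (tr in seq_len(n_trials)) {
        id <- sprintf("%s_%s_t%d", pid[i], cond, tr)
        angles <- generate_joint_waveforms(group[i], cond, effects,
                                           platform, participant = part)
        entry <- list(platform = disp, angles = angles,
                      markers = NULL, forces = NULL, cop = NULL)
        if (include_markers) {
          entry$markers <- forward_kinematics(
            angles, template,
            platform_disp = if (cond == "moving") disp else NULL,
            side = side[i], marker_noise_sd = marker_noise_sd)
        }
        if (include_forces) {
          gen <- generate_cop_and_forces(group[i], cond, effects, foot_rect,
                                         platform, sample_rate = force_rate)
          entry$forces <- gen$record
          entry$cop <- gen$cop
        }
        trials[[id]] <- entry
      }
    }
  }
  structure(list(manifest = manifest, trials = trials,
                 platform = platform, effects = effects,
                 template = template, foot_rect = foot_rect,
                 seed = seed, force_rate = force_rate),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  m <- x$manifest
  cat("synthetic_cohort:", length(unique(m$participant)), "participants (",
      sum(!duplicated(m$participant) & m$group == "CAI"), "CAI /",
      sum(!duplicated(m$participant) & m$group == "HC"), "HC ),",
      nrow(m), "trials,",
      "conditions:", paste(unique(m$condition), collapse = "/"), "\n")
  invisible(x)
}
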