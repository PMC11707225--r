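#' Process one balance trial
#'
#' Runs the conditioning and measurement chain for a single trial:
#' markers are low-pass filtered (4th order, 10 Hz, zero phase) and joint
#' angles extracted from segment frames (the stored ground-truth angles
#' are filtered and used directly when the trial carries no markers);
#' force-plate channels are filtered at the plate rate, spline-downsampled
#' to the marker rate, and converted to a centre of pressure; everything
#' is trimmed to the middle 10-s window anchored on the platform's medial
#' zero crossing (moving) or centred (static). Time-to-boundary uses the
#' foot rectangle built from the trial's four foot-border markers in the
#' support-surface frame (the template rectangle when markers are
#' absent).
#'
#' @param trial one cohort trial (list with `platform`, `angles`, and
#'   optionally `markers`, `forces`).
#' @param side stance side for this trial.
#' @param condition `"static"` or `"moving"`.
#' @param template the [body_template()] used for extraction.
#' @param cutoff,filter_order filter parameters.
#' @param target_rate common analysis rate, Hz.
#' @param velocity_mode angular-velocity definition, see
#'   [angular_velocity()].
#' @param use_markers extract angles from markers when available
#'   (default) or always use the stored ground-truth angles.
#' @return list with `angles` (trimmed tensor), `discrete`
#'   ([discrete_measures()]), `ttb` ([ttb_summary()]), `sway`
#'   ([sway_summary()]), `window` (the [trim_to_middle_10s()] window).
#' @export
process_trial <- function(trial, side = "right", condition = "static",
                          template = body_template(), cutoff = 10,
                          filter_order = 4, target_rate = 100,
                          velocity_mode = "first", use_markers = TRUE) {
  moving <- condition == "moving"
  platform_disp <- trial$platform
  if (use_markers && !is.null(trial$markers)) {
    markers <- butterworth_lowpass(trial$markers, cutoff, filter_order)
    angles <- extract_joint_angles(markers, template, side)
  } else {
    markers <- NULL
    angles <- joint_angle_tensor(
      butterworth_lowpass(unclass(trial$angles), cutoff, filter_order,
                          sample_rate = attr(trial$angles, "sample_rate")),
      attr(trial$angles, "sample_rate"))
  }
  window <- trim_to_middle_10s(nrow(angles), attr(angles, "sample_rate"),
                               if (moving) platform_disp else NULL, side)
  angles_tr <- apply_trim(angles, window)
  vel <- angular_velocity(angles_tr, mode = velocity_mode)
  discrete <- discrete_measures(angles_tr, vel)

  ttb <- sway <- NULL
  if (!is.null(trial$forces)) {
    force_rate <- attr(trial$forces, "sample_rate")
    filt <- trial$forces
    for (col in c("Fx", "Fy", "Fz", "Mx", "My", "Mz")) {
      filt[[col]] <- butterworth_lowpass(filt[[col]], cutoff, filter_order,
                                         sample_rate = force_rate)
    }
    attr(filt, "sample_rate") <- force_rate
    cop <- compute_cop(filt)
    cop <- spline_downsample(cop, target_rate, sample_rate = force_rate)
    boundary <- trial_foot_boundary(markers, platform_disp, template)
    cop_ff <- cop_to_foot_frame(cop, boundary)
    cop_tr <- apply_trim(cop_ff, window)
    series <- ttb_ml(cop_tr, boundary, sample_rate = target_rate)
    ttb <- ttb_summary(series)
    sway <- sway_summary(cop_tr, sample_rate = target_rate)
  }
  list(angles = angles_tr, discrete = discrete, ttb = ttb, sway = sway,
       window = window)
}

# foot rectangle for a trial: from the filtered foot markers expressed in
# the support-surface frame (platform displacement removed), or from the
# template when no markers are available
trial_foot_boundary <- function(markers, platform_disp, template) {
  if (is.null(markers)) {
    m <- template$segments$foot$markers
    b <- foot_boundary(t(m["mt1", ]), t(m["mt5", ]), t(m["toe", ]),
                       t(m["cal", ]))
    return(b)
  }
  surf <- function(label) {
    xyz <- marker_xyz(markers, label)
    if (!is.null(platform_disp)) xyz[, 1] <- xyz[, 1] - platform_disp
    xyz
  }
  foot_boundary(surf("mt1"), surf("mt5"), surf("toe"), surf("cal"))
}

#' Run the full balance analysis on a cohort
#'
#' Per-trial processing ([process_trial()]) followed by the study-level
#' aggregation: trial-averaged time-to-boundary and sway summaries per
#' participant and condition; trial-averaged discrete kinematics; the
#' waveform PCA per condition (intra-participant averages, z-scoring,
#' 90% variance retention, group t-tests on scores, leave-one-out
#' surrogate validation of the strongest group-separating component, and
#' its group-mean waveform reconstruction); the mixed 2 x 2 ANOVAs on the
#' three time-to-boundary measures; score-balance correlations; and the
#' stepwise regression of the mean of time-to-boundary minima on the 12
#' RMS angular-velocity channels.
#'
#' @param cohort a [generate_cohort()] result (or an equivalently shaped
#'   list read from disk).
#' @param variance_threshold PCA retention threshold.
#' @param regression_condition condition whose data feed the stepwise
#'   regression (default `"moving"`).
#' @param velocity_mode angular-velocity definition.
#' @param use_markers extract angles from markers (default) or use the
#'   stored ground-truth angle tensors.
#' @param run_loo run the leave-one-out surrogate validation (the most
#'   expensive stage).
#' @return an object of class `balance_analysis`; see the individual
#'   stage functions for the component structures.
#' @export
run_balance_pipeline <- function(cohort, variance_threshold = 0.90,
                                 regression_condition = "moving",
                                 velocity_mode = "first",
                                 use_markers = TRUE, run_loo = TRUE) {
  m <- cohort$manifest
  template <- cohort$template %||% body_template()
  conditions <- unique(m$condition)
  per_trial <- vector("list", nrow(m))
  names(per_trial) <- m$trial_id
  for (i in seq_len(nrow(m))) {
    per_trial[[i]] <- process_trial(cohort$trials[[m$trial_id[i]]],
                                    side = m$side[i],
                                    condition = m$condition[i],
                                    template = template,
                                    velocity_mode = velocity_mode,
                                    use_markers = use_markers)
  }

  # participant x condition aggregation (means over the 3 trials)
  keys <- unique(m[c("participant", "group", "condition")])
  rownames(keys) <- NULL
  stability <- keys
  stability$ttb_mean_min <- stability$ttb_abs_min <-
    stability$ttb_sd_min <- stability$sd_amp <-
    stability$sway_velocity <- NA_real_
  rms_mat <- matrix(NA_real_, nrow(keys), 12L,
                    dimnames = list(NULL, channel_names()))
  rom_mat <- rms_mat
  for (i in seq_len(nrow(keys))) {
    ids <- m$trial_id[m$participant == keys$participant[i] &
                        m$condition == keys$condition[i]]
    res <- per_trial[ids]
    if (!is.null(res[[1]]$ttb)) {
      stability$ttb_mean_min[i] <-
        mean(vapply(res, function(r) r$ttb$mean_of_minima, 1), na.rm = TRUE)
      stability$ttb_abs_min[i] <-
        mean(vapply(res, function(r) r$ttb$absolute_minimum, 1), na.rm = TRUE)
      stability$ttb_sd_min[i] <-
        mean(vapply(res, function(r) r$ttb$sd_of_minima, 1), na.rm = TRUE)
      stability$sd_amp[i] <-
        mean(vapply(res, function(r) r$sway$sd_amp, 1))
      stability$sway_velocity[i] <-
        mean(vapply(res, function(r) r$sway$sway_velocity, 1))
    }
    rom_mat[i, ] <- rowMeans(vapply(res, function(r) r$discrete$rom,
                                    numeric(12L)))
    rms_mat[i, ] <- rowMeans(vapply(res, function(r) r$discrete$rms_velocity,
                                    numeric(12L)))
  }
  kinematics <- data.frame(keys, rom = I(rom_mat), rms_velocity = I(rms_mat))

  # per-condition waveform PCA
  pca <- list()
  for (cond in conditions) {
    sel <- keys$condition == cond
    parts <- keys$participant[sel]
    groups <- keys$group[sel]
    averages <- lapply(parts, function(p) {
      ids <- m$trial_id[m$participant == p & m$condition == cond]
      intra_participant_average(lapply(per_trial[ids], `[[`, "angles"))
    })
    names(averages) <- parts
    input <- assemble_and_standardize(averages)
    fit <- fit_pca(input, variance_threshold, groups = groups)
    tests <- test_group_scores(fit, groups)
    top <- tests$component[which.min(tests$p)]
    loo <- if (run_loo) {
      loo_surrogate_validation(input, groups, fit$loadings[top, ],
                               variance_threshold)
    } else NULL
    recon <- reconstruct_group_waveforms(fit, input, components = top,
                                         groups = groups)
    pca[[cond]] <- list(input = input, fit = fit, tests = tests,
                        top_component = top, loo = loo,
                        reconstruction = recon, groups = groups,
                        participants = parts)
  }

  # inferential layer
  anova <- NULL
  if (length(conditions) == 2L && all(!is.na(stability$ttb_mean_min))) {
    anova <- lapply(c(ttb_mean_min = "ttb_mean_min",
                      ttb_abs_min = "ttb_abs_min",
                      ttb_sd_min = "ttb_sd_min"), function(v) {
      mixed_anova_2x2(stability, value = v)
    })
  }
  regression <- correlations <- NULL
  if (regression_condition %in% conditions &&
      all(!is.na(stability$ttb_mean_min[keys$condition == regression_condition]))) {
    sel <- keys$condition == regression_condition
    Xr <- as.data.frame(rms_mat[sel, , drop = FALSE])
    regression <- stepwise_regression(stability$ttb_mean_min[sel], Xr)
    pc <- pca[[regression_condition]]
    sc <- pc$fit$scores[, pc$top_component]
    correlations <- list(
      sd_amp = correlate_scores_with_balance(
        sc, stability$sd_amp[sel], pc$groups),
      sway_velocity = correlate_scores_with_balance(
        sc, stability$sway_velocity[sel], pc$groups))
  }
  structure(list(stability = stability, kinematics = kinematics, pca = pca,
                 anova = anova, regression = regression,
                 correlations = correlations, manifest = m),
            class = "balance_analysis")
}

#' @export
print.balance_analysis <- function(x, ...) {
  cat("balance_analysis:", length(unique(x$manifest$participant)),
      "participants,", nrow(x$manifest), "trials\n")
  if (!is.null(x$anova)) {
    cat("\nTTB mean-of-minima mixed ANOVA:\n")
    print(x$anova$ttb_mean_min$effects, row.names = FALSE, digits = 4)
  }
  for (cond in names(x$pca)) {
    p <- x$pca[[cond]]
    cat("\n", cond, " PCA: ", p$fit$retained_k, " components retained; ",
        "strongest group component PC", p$top_component,
        " (p = ", signif(p$tests$p[p$tests$component == p$top_component], 3),
        ")\n", sep = "")
  }
  invisible(x)
}
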