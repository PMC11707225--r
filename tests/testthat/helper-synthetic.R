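# shared fixtures built in code

random_rotation <- function() {
  # QR of a Gaussian matrix with positive diagonal convention, det +1
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

random_angle_tensor <- function(n = 150, sd = 12, rate = 100) {
  joint_angle_tensor(matrix(rnorm(n * 12, 0, sd), n, 12), rate)
}

# a small two-condition cohort for pipeline-level tests
tiny_cohort <- function(n_per_group = 3, seed = 11, force_rate = 400, ...) {
  generate_cohort(n_per_group = n_per_group, seed = seed,
                  force_rate = force_rate, ...)
}

# angle-waveform mini cohort (no markers/forces) trimmed and averaged,
# returning the assembled PCA input and groups
waveform_pca_input <- function(n_per_group, platform, effects,
                               condition = "static", n_trials = 3) {
  groups <- rep(c("CAI", "HC"), each = n_per_group)
  averages <- lapply(seq_along(groups), function(i) {
    part <- posturekit:::draw_participant(groups[i], effects)
    trials <- lapply(seq_len(n_trials), function(tr) {
      generate_joint_waveforms(groups[i], condition, effects, platform,
                               participant = part)
    })
    intra_participant_average(trials)
  })
  names(averages) <- sprintf("S%02d", seq_along(groups))
  list(input = assemble_and_standardize(averages), groups = groups)
}
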