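# small centred matrix with a planted rank-1 pattern (centred, not
# variance-scaled: scaling to unit column variance would whiten the
# pattern shape out of the loadings)
planted_input <- function(n = 12, p = 300, effect = 3, noise = 0.05,
                          pattern = NULL) {
  if (is.null(pattern)) pattern <- sin(seq(0, 3 * pi, length.out = p))
  scores <- rnorm(n, 0, effect)
  X <- outer(scores, pattern) + matrix(rnorm(n * p, 0, noise), n)
  scale(X, scale = FALSE)
}

test_that("intra-participant averaging is the pointwise trial mean", {
  a <- random_angle_tensor(n = 50)
  expect_equal(unclass(intra_participant_average(list(a, a, a))),
               unclass(a))

  consts <- lapply(c(0, 3, 6), function(v) {
    joint_angle_tensor(matrix(v, 20, 12), 100)
  })
  expect_true(all(unclass(intra_participant_average(consts)) == 3))

  withr::local_seed(21)
  trials <- replicate(3, random_angle_tensor(n = 30), simplify = FALSE)
  direct <- (unclass(trials[[1]]) + unclass(trials[[2]]) +
               unclass(trials[[3]])) / 3
  expect_equal(unclass(intra_participant_average(trials)), direct,
               tolerance = 1e-12)

  bad <- list(random_angle_tensor(n = 30), random_angle_tensor(n = 31))
  expect_error(intra_participant_average(bad), "alignment error")
})

test_that("assembly lays out channel-major variables and z-scores columns", {
  withr::local_seed(22)
  n_time <- 40
  averages <- lapply(1:6, function(i) {
    joint_angle_tensor(matrix(rnorm(n_time * 12), n_time, 12), 100)
  })
  names(averages) <- sprintf("S%02d", 1:6)
  input <- assemble_and_standardize(averages)
  expect_equal(dim(input$z), c(6L, 12L * n_time))
  # variable (c-1)*T + t is channel c, time t
  c_idx <- 5L; t_idx <- 17L
  raw_col <- input$raw[, (c_idx - 1L) * n_time + t_idx]
  direct <- vapply(averages, function(a) unclass(a)[t_idx, c_idx], 1)
  expect_equal(unname(raw_col), unname(direct))
  # z-scoring uses the sample SD across participants
  expect_equal(unname(input$z[, 1]),
               unname((input$raw[, 1] - mean(input$raw[, 1])) /
                        sd(input$raw[, 1])))
  expect_equal(max(abs(colMeans(input$z))), 0, tolerance = 1e-12)

  # the {1,2,3} column example
  expect_equal((c(1, 2, 3) - 2) / sd(c(1, 2, 3)), c(-1, 0, 1))

  # a constant channel is dropped and reported
  averages2 <- averages
  averages2 <- lapply(averages2, function(a) {
    m <- unclass(a); m[, 2] <- 7; joint_angle_tensor(m, 100)
  })
  expect_message(input2 <- assemble_and_standardize(averages2), "dropped")
  expect_equal(length(input2$dropped), n_time)
  expect_equal(ncol(input2$z), 11L * n_time)
})

test_that("PCA retains to the variance threshold and recovers planted patterns", {
  withr::local_seed(23)
  pattern <- sin(seq(0, 3 * pi, length.out = 300))
  Z <- planted_input(pattern = pattern)
  fit <- fit_pca(Z)
  expect_equal(fit$retained_k, 1L)
  expect_gt(abs(cor(fit$loadings[1, ], pattern)), 0.99)

  # loadings orthonormal, variance fractions non-increasing, cumulative
  # crossing exactly at retained_k
  G <- fit$loadings[1:11, ] %*% t(fit$loadings[1:11, ])
  expect_lt(max(abs(G - diag(11))), 1e-9)
  expect_true(all(diff(fit$var_explained) < 1e-12))
  cum <- cumsum(fit$var_explained)
  expect_gte(cum[fit$retained_k], 0.90)
  if (fit$retained_k > 1L) expect_lt(cum[fit$retained_k - 1L], 0.90)

  # full-basis reconstruction reproduces the standardized input
  rec <- fit$scores %*% fit$loadings
  expect_lt(max(abs(rec - Z)), 1e-9)

  expect_error(fit_pca(Z[1:2, ]), "insufficient data")
})

test_that("participant permutation permutes scores and changes no test", {
  withr::local_seed(24)
  Z <- planted_input(n = 14)
  groups <- rep(c("CAI", "HC"), each = 7)
  fit <- fit_pca(Z, groups = groups)
  tests <- test_group_scores(fit, groups)

  perm <- sample(14)
  fit_p <- fit_pca(Z[perm, ], groups = groups[perm])
  tests_p <- test_group_scores(fit_p, groups[perm])
  expect_equal(abs(fit_p$scores[, 1]), abs(fit$scores[perm, 1]),
               tolerance = 1e-8)
  expect_equal(tests_p$p, tests$p, tolerance = 1e-8)
  expect_equal(abs(tests_p$t), abs(tests$t), tolerance = 1e-8)
})

test_that("sign convention orients components by the reference group", {
  withr::local_seed(25)
  Z <- planted_input(n = 16)
  groups <- rep(c("CAI", "HC"), each = 8)
  fit <- fit_pca(Z, groups = groups)
  for (j in seq_len(fit$retained_k)) {
    expect_gte(mean(fit$scores[groups == "HC", j]), 0)
  }
  # flipping a loading and its scores changes neither reconstructions
  # nor p values (orientation is a pure convention)
  f2 <- fit
  f2$scores[, 1] <- -f2$scores[, 1]
  f2$loadings[1, ] <- -f2$loadings[1, ]
  expect_equal(f2$scores %*% f2$loadings, fit$scores %*% fit$loadings,
               tolerance = 1e-12)
  expect_equal(test_group_scores(f2, groups)$p,
               test_group_scores(fit, groups)$p)
})

test_that("group score tests report t, p and Cohen's d", {
  fit <- list(scores = cbind(c(1, 2, 3, 3, 4, 5)), retained_k = 1L,
              loadings = matrix(1, 1, 1))
  class(fit) <- "pca_result"
  groups <- rep(c("CAI", "HC"), each = 3)
  out <- test_group_scores(fit, groups)
  expect_equal(out$d, -2)           # CAI - HC = -2 pooled SDs
  expect_equal(out$df, 4)

  same <- fit; same$scores <- cbind(rep(c(1, 2, 3), 2))
  out2 <- test_group_scores(same, groups)
  expect_equal(out2$t, 0)
  expect_equal(out2$d, 0)

  expect_error(test_group_scores(fit, c("A", "A", "A", "A", "A", "B")),
               "insufficient group")
})

test_that("waveform reconstruction inverts the z-scoring", {
  withr::local_seed(26)
  n_time <- 30
  averages <- lapply(1:8, function(i) {
    joint_angle_tensor(matrix(rnorm(n_time * 12, 10, 3), n_time, 12), 100)
  })
  names(averages) <- sprintf("S%02d", 1:8)
  input <- assemble_and_standardize(averages)
  groups <- rep(c("CAI", "HC"), 4)
  fit <- fit_pca(input, groups = groups)

  # zero scores -> the grand-mean waveforms
  k_all <- nrow(fit$loadings)
  grand <- reconstruct_group_waveforms(fit, input,
                                       scores = rep(0, k_all),
                                       components = seq_len(k_all))
  expect_equal(as.vector(grand), unname(input$mu), tolerance = 1e-9)

  # a participant's full score vector -> their averaged waveforms
  rec <- reconstruct_group_waveforms(fit, input, scores = fit$scores[3, ],
                                     components = seq_len(k_all))
  expect_lt(max(abs(rec - unclass(averages[[3]]))), 1e-9)

  # per-group reconstruction returns one tensor per group
  gr <- reconstruct_group_waveforms(fit, input, groups = groups,
                                    components = 1L)
  expect_named(gr, c("CAI", "HC"))
  expect_equal(dim(gr$CAI), c(n_time, 12L))

  expect_error(reconstruct_group_waveforms(fit, input, scores = 1,
                                           components = 99L), "index error")
})

test_that("leave-one-out surrogates refit, match and classify", {
  withr::local_seed(27)
  platform <- platform_spec(duration = 1.2, sample_rate = 50)
  eff <- group_effect_spec(offset_sd = 1.5, noise_sd = 0.8)
  wf <- waveform_pca_input(5, platform, eff)
  fit <- fit_pca(wf$input, groups = wf$groups)
  tests <- test_group_scores(fit, wf$groups)
  top <- tests$component[which.min(tests$p)]
  loo <- loo_surrogate_validation(wf$input, wf$groups, fit$loadings[top, ])
  expect_equal(nrow(loo$table), 10L)
  expect_equal(sum(loo$counts), 10)
  expect_true(all(loo$table$loading_cor >= 0))
  expect_setequal(unique(loo$table$class) %in%
                    c("significant", "marginal", "non-significant"), TRUE)
})

test_that("score-balance correlations recover exact and planted couplings", {
  withr::local_seed(28)
  s <- rnorm(20)
  out <- correlate_scores_with_balance(s, 2 * s + 1)
  expect_equal(out$r, 1, tolerance = 1e-12)

  groups <- rep(c("CAI", "HC"), 10)
  metric <- 0.8 * s + rnorm(20, 0, 0.3)
  out2 <- correlate_scores_with_balance(s, metric, groups)
  expect_equal(out2$scope, c("all", "CAI", "HC"))
  expect_gt(out2$r[1], 0.5)

  expect_error(correlate_scores_with_balance(s, rep(1, 20)),
               "undefined correlation")
  expect_error(correlate_scores_with_balance(s, metric[1:5]), "paired")
})
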