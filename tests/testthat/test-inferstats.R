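test_that("Cohen's d matches hand computation and is scale invariant", {
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), 2)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- rnorm(10); b <- rnorm(12, 1)
  expect_equal(cohens_d(3 * a, 3 * b), cohens_d(a, b), tolerance = 1e-12)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "undefined effect")
  expect_error(cohens_d(1, c(1, 2)), ">= 2")
})

# direct sums-of-squares oracle for the mixed 2x2 design
ss_oracle <- function(d) {
  gm <- mean(d$value)
  cell <- aggregate(value ~ group + condition, d, mean)
  gmean <- aggregate(value ~ group, d, mean)
  cmean <- aggregate(value ~ condition, d, mean)
  pmean <- aggregate(value ~ participant + group, d, mean)
  n_per_cell <- nrow(d) / 4
  n_cond <- 2
  ss_group <- n_cond * n_per_cell * sum((gmean$value - gm)^2)
  ss_subj <- n_cond * sum((pmean$value -
                             gmean$value[match(pmean$group, gmean$group)])^2)
  ss_cond <- 2 * n_per_cell * sum((cmean$value - gm)^2)
  cell$gc <- cell$value
  exp_add <- gmean$value[match(cell$group, gmean$group)] +
    cmean$value[match(cell$condition, cmean$condition)] - gm
  ss_int <- n_per_cell * sum((cell$gc - exp_add)^2)
  fitted <- cell$gc[match(paste(d$group, d$condition),
                          paste(cell$group, cell$condition))] +
    (pmean$value[match(d$participant, pmean$participant)] -
       gmean$value[match(d$group, gmean$group)])
  ss_err_w <- sum((d$value - fitted)^2)
  list(pes_group = ss_group / (ss_group + ss_subj),
       pes_cond = ss_cond / (ss_cond + ss_err_w),
       pes_int = ss_int / (ss_int + ss_err_w))
}

test_that("mixed ANOVA partial eta squared equals the SS decomposition", {
  # hand-built 4-participant data set
  d4 <- data.frame(
    participant = rep(c("a", "b", "c", "d"), each = 2),
    group = rep(c("CAI", "CAI", "HC", "HC"), each = 2),
    condition = rep(c("static", "moving"), 4),
    value = c(1.1, 0.4, 1.3, 0.5, 1.8, 0.5, 1.6, 0.6))
  res <- mixed_anova_2x2(d4)
  orc <- ss_oracle(d4)
  expect_equal(res$effects$pes, unname(unlist(orc)), tolerance = 1e-9)

  # a larger random balanced design
  withr::local_seed(31)
  n <- 10
  d <- expand.grid(participant = sprintf("p%02d", 1:(2 * n)),
                   condition = c("static", "moving"))
  d$group <- ifelse(as.integer(sub("p", "", d$participant)) <= n, "CAI", "HC")
  d$value <- rnorm(nrow(d)) + (d$group == "CAI") * 0.5 +
    (d$condition == "moving") * -0.8 +
    (d$group == "CAI" & d$condition == "static") * 0.4
  res2 <- mixed_anova_2x2(d)
  orc2 <- ss_oracle(d)
  expect_equal(res2$effects$pes, unname(unlist(orc2)), tolerance = 1e-9)
  expect_true(all(res2$effects$pes >= 0 & res2$effects$pes <= 1))

  # equal cell means with balanced within-cell variation: every F is 0
  d0 <- expand.grid(participant = sprintf("q%d", 1:8),
                    condition = c("static", "moving"))
  d0$group <- rep(rep(c("CAI", "HC"), each = 4), 2)
  base <- rep(c(1, 2, 3, 4), 2)
  d0$value <- base[match(d0$participant, sprintf("q%d", 1:8))]
  # within-group static perturbations that cancel in every margin
  d0$value[d0$condition == "static" & d0$participant %in% c("q1", "q5")] <-
    d0$value[d0$condition == "static" & d0$participant %in% c("q1", "q5")] + 0.3
  d0$value[d0$condition == "static" & d0$participant %in% c("q2", "q6")] <-
    d0$value[d0$condition == "static" & d0$participant %in% c("q2", "q6")] - 0.3
  res0 <- mixed_anova_2x2(d0)
  expect_true(all(res0$effects$F < 1e-9))
  expect_true(all(res0$effects$pes < 1e-9))
})

test_that("Bonferroni post hocs double raw p values and cap at one", {
  withr::local_seed(32)
  d <- expand.grid(participant = sprintf("p%02d", 1:12),
                   condition = c("static", "moving"))
  d$group <- rep(rep(c("CAI", "HC"), each = 6), 2)
  d$value <- rnorm(nrow(d))
  res <- mixed_anova_2x2(d)
  expect_true(all(res$posthoc$p_adj >= res$posthoc$p_raw))
  expect_true(all(res$posthoc$p_adj <= 1))
  expect_equal(res$posthoc$p_adj,
               pmin(1, 2 * res$posthoc$p_raw))
  expect_equal(nrow(res$posthoc), 4L)

  expect_error(mixed_anova_2x2(d[-1, ]), "design error")
})

test_that("stepwise regression recovers a planted single predictor", {
  withr::local_seed(33)
  first_hits <- member_hits <- 0L
  runs <- 30L
  for (r in seq_len(runs)) {
    n <- 46
    X <- as.data.frame(matrix(rnorm(n * 12), n,
                              dimnames = list(NULL, channel_names())))
    y <- 2 * X[[1]] + rnorm(n, 0, 2 / 5)   # SNR 5
    m <- stepwise_regression(y, X)
    if (length(m$selected) && m$selected[1] == names(X)[1]) {
      first_hits <- first_hits + 1L
    }
    if (names(X)[1] %in% m$selected) member_hits <- member_hits + 1L
  }
  # the true predictor always enters, and enters first
  expect_gte(member_hits, ceiling(0.95 * runs))
  expect_gte(first_hits, ceiling(0.95 * runs))
})

test_that("stepwise null entry rate matches the family-wise expectation", {
  withr::local_seed(34)
  runs <- 200L
  entered <- logical(runs)
  for (r in seq_len(runs)) {
    n <- 46
    X <- as.data.frame(matrix(rnorm(n * 12), n,
                              dimnames = list(NULL, paste0("v", 1:12))))
    y <- rnorm(n)
    entered[r] <- length(stepwise_regression(y, X)$selected) > 0
  }
  # ~ 1 - 0.95^12 = 0.46 under independence
  expect_gt(mean(entered), 0.30)
  expect_lt(mean(entered), 0.62)
})

test_that("stepwise recovers a planted three-predictor sign pattern", {
  withr::local_seed(35)
  n <- 46
  X <- as.data.frame(matrix(rnorm(n * 12), n,
                            dimnames = list(NULL, channel_names())))
  y <- -5 * X$ankle_sagittal - 2.4 * X$ankle_frontal +
    1.6 * X$hip_horizontal + rnorm(n, 0, 1.5)
  m <- stepwise_regression(y, X)
  expect_true(all(c("ankle_sagittal", "ankle_frontal", "hip_horizontal")
                  %in% m$selected))
  cf <- m$coefficients
  expect_lt(cf$beta[cf$term == "ankle_sagittal"], 0)
  expect_lt(cf$beta[cf$term == "ankle_frontal"], 0)
  expect_gt(cf$beta[cf$term == "hip_horizontal"], 0)
  # the cumulative R-squared ladder is non-decreasing over additions
  adds <- m$steps[m$steps$action == "add", ]
  expect_true(all(diff(adds$r_squared) >= -1e-12))
  # refitting the final model reproduces the reported coefficients
  refit <- lm(y ~ ., data = cbind(y = y, X[m$selected]))
  expect_equal(sort(unname(coef(refit)[-1])), sort(cf$beta[-1]),
               tolerance = 1e-12)
})

test_that("stepwise flags perfect collinearity among candidates", {
  withr::local_seed(36)
  n <- 30
  X <- data.frame(a = rnorm(n))
  X$b <- 2 * X$a
  y <- X$a + rnorm(n, 0, 0.1)
  expect_error(stepwise_regression(y, X), "collinearity error")
})

test_that("normality diagnostics run per group", {
  withr::local_seed(37)
  x <- rnorm(40)
  out <- normality_check(x, rep(c("CAI", "HC"), 20))
  expect_equal(out$scope, c("CAI", "HC"))
  expect_true(all(out$p > 0 & out$p <= 1))
})
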