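#' Intra-participant average of repeated trials
#'
#' Pointwise mean across a participant's trial repetitions, per channel
#' and time point.
#'
#' @param trials list of [joint_angle_tensor()]s (or matrices) of equal
#'   dimension.
#' @return the averaged tensor/matrix.
#' @export
intra_participant_average <- function(trials) {
  if (!length(trials)) stop("no trials supplied")
  dims <- lapply(trials, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]]))) {
    stop("alignment error: trials differ in dimension")
  }
  acc <- Reduce(`+`, lapply(trials, unclass)) / length(trials)
  if (inherits(trials[[1]], "joint_angle_tensor")) {
    joint_angle_tensor(acc, attr(trials[[1]], "sample_rate"))
  } else acc
}

#' Assemble and z-score the participants-by-variables matrix
#'
#' Builds the PCA input: one row per participant, columns laid out
#' channel-major then time (variable `(c - 1) * T + t` is time point `t`
#' of canonical channel `c`), so 12 channels x 1,000 time points give
#' 12,000 variables. Each column is z-scored across participants
#' (sample SD); columns with SD below `1e-12` are dropped and reported.
#'
#' @param averages named list (one entry per participant) of averaged
#'   T x 12 angle tensors from [intra_participant_average()].
#' @return list of class `pca_input`: `z` (n x p standardized matrix),
#'   `raw` (n x p raw matrix), `mu`, `sigma` (per-variable mean / SD over
#'   the retained columns), `dropped` (indices of dropped variables),
#'   `n_time`, `participants`.
#' @export
assemble_and_standardize <- function(averages) {
  if (!length(averages)) stop("assembly error: no participants")
  if (is.null(names(averages))) {
    names(averages) <- sprintf("P%02d", seq_along(averages))
  }
  dims <- lapply(averages, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]]))) {
    stop("assembly error: participants differ in dimension")
  }
  n_time <- dims[[1]][1]
  if (dims[[1]][2] != 12L) stop("assembly error: expected 12 channels")
  X <- t(vapply(averages, function(a) as.vector(unclass(a)),
                numeric(n_time * 12L)))
  vn <- paste(rep(channel_names(), each = n_time),
              rep(seq_len(n_time), 12L), sep = ".")
  colnames(X) <- vn
  mu <- colMeans(X)
  sigma <- apply(X, 2L, stats::sd)
  dropped <- which(sigma < 1e-12)
  keep <- setdiff(seq_len(ncol(X)), dropped)
  if (length(dropped)) {
    message(length(dropped), " constant variable(s) dropped before z-scoring")
  }
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2L, mu[keep]), 2L,
             sigma[keep], `/`)
  structure(list(z = Z, raw = X, mu = mu[keep], sigma = sigma[keep],
                 dropped = dropped, n_time = n_time,
                 participants = names(averages)),
            class = "pca_input")
}

#' Fit the waveform PCA and retain 90% of variance
#'
#' Singular value decomposition of the participant-standardized matrix.
#' Principal component vectors (PCVs, the loadings) and scores (PCSs) are
#' extracted for all components; `retained_k` is the smallest number of
#' leading components whose cumulative explained variance reaches
#' `variance_threshold`. When `groups` are supplied each component's sign
#' is fixed so the reference group's mean score is non-negative
#' (orientation convention: healthy controls score positive); otherwise
#' the largest-magnitude loading entry is made positive.
#'
#' @param input a [assemble_and_standardize()] result (or an already
#'   centred numeric matrix).
#' @param variance_threshold cumulative explained-variance target
#'   (default 0.90).
#' @param groups optional factor/character vector of group labels per
#'   participant, used for the sign convention.
#' @param ref_group reference group for the sign convention (default
#'   `"HC"` when present).
#' @return an object of class `pca_result`: `loadings` (components x
#'   variables, orthonormal rows), `scores` (participants x components),
#'   `var_explained` (fractions), `retained_k`, `sign_ref`.
#' @export
fit_pca <- function(input, variance_threshold = 0.90, groups = NULL,
                    ref_group = NULL) {
  Z <- if (inherits(input, "pca_input")) input$z else as.matrix(input)
  n <- nrow(Z)
  if (n < 3L) stop("insufficient data: PCA needs >= 3 participants")
  sv <- svd(Z, nu = n, nv = n)
  d <- sv$d[seq_len(min(dim(Z)))]
  frac <- d^2 / sum(d^2)
  cum <- cumsum(frac)
  retained_k <- which(cum >= variance_threshold)[1L]
  scores <- sv$u %*% diag(sv$d, n, n)
  loadings <- t(sv$v)                  # components x variables
  if (!is.null(groups)) {
    groups <- as.character(groups)
    if (is.null(ref_group)) {
      ref_group <- if ("HC" %in% groups) "HC" else sort(unique(groups))[1L]
    }
    ref <- groups == ref_group
    for (j in seq_len(ncol(scores))) {
      if (mean(scores[ref, j]) < 0) {
        scores[, j] <- -scores[, j]
        loadings[j, ] <- -loadings[j, ]
      }
    }
  } else {
    ref_group <- NA_character_
    for (j in seq_len(nrow(loadings))) {
      lead <- which.max(abs(loadings[j, ]))
      if (loadings[j, lead] < 0) {
        scores[, j] <- -scores[, j]
        loadings[j, ] <- -loadings[j, ]
      }
    }
  }
  rownames(scores) <- rownames(Z)
  structure(list(loadings = loadings, scores = scores,
                 var_explained = frac, retained_k = retained_k,
                 variance_threshold = variance_threshold,
                 sign_ref = ref_group),
            class = "pca_result")
}

#' Group t-tests on the principal component scores
#'
#' Independent two-sample t-tests (pooled variance by default) on each
#' retained component's scores, with Cohen's d (pooled SD). No
#' multiple-testing correction is applied; the number of tests performed
#' is reported alongside so readers can judge the family size.
#'
#' @param result a [fit_pca()] result.
#' @param groups group label per participant (two levels).
#' @param components components to test (default the retained set).
#' @param var_equal pooled (`TRUE`, default) or Welch t-test.
#' @return data.frame `component, t, df, p, d, mean_<g1>, mean_<g2>` with
#'   attribute `n_tests`; `d` is standardized mean difference
#'   `g1 - g2` in the order of sorted unique labels (CAI before HC).
#' @export
test_group_scores <- function(result, groups, components = NULL,
                              var_equal = TRUE) {
  stopifnot(inherits(result, "pca_result"))
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  if (length(lv) != 2L) stop("exactly two groups are required")
  if (min(table(groups)) < 2L) stop("insufficient group: need >= 2 per group")
  if (is.null(components)) components <- seq_len(result$retained_k)
  rows <- lapply(components, function(j) {
    a <- result$scores[groups == lv[1], j]
    b <- result$scores[groups == lv[2], j]
    tt <- stats::t.test(a, b, var.equal = var_equal)
    data.frame(component = j, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               d = cohens_d(b, a),   # standardized lv1 - lv2
               m1 = mean(a), m2 = mean(b))
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "m1"] <- paste0("mean_", lv[1])
  names(out)[names(out) == "m2"] <- paste0("mean_", lv[2])
  attr(out, "n_tests") <- length(components)
  out
}

#' Reconstruct joint-angle waveforms from component scores
#'
#' Maps a score vector back through the selected loadings and inverse
#' z-scoring: `X_hat = mu + sigma * (scores %*% loadings)`, reshaped to a
#' T x 12 angle tensor. With `groups` supplied, reconstructs one waveform
#' set per group from the group-mean scores (the usual interpretation
#' figure); with a full score vector of one participant and all
#' components it reproduces that participant's averaged waveforms.
#'
#' @param result a [fit_pca()] result.
#' @param input the [assemble_and_standardize()] result used for the fit.
#' @param scores numeric score vector over `components`, or `NULL` when
#'   `groups` is given.
#' @param components component indices (default the retained set).
#' @param groups optional group labels; reconstructs per-group waveforms
#'   from mean scores.
#' @return a [joint_angle_tensor()]-shaped matrix (degrees), or a named
#'   list of them (one per group).
#' @export
reconstruct_group_waveforms <- function(result, input, scores = NULL,
                                        components = NULL, groups = NULL) {
  stopifnot(inherits(result, "pca_result"), inherits(input, "pca_input"))
  if (is.null(components)) components <- seq_len(result$retained_k)
  if (any(components < 1L | components > nrow(result$loadings))) {
    stop("index error: unknown component index")
  }
  rebuild <- function(sc) {
    zhat <- as.numeric(matrix(sc, 1L) %*%
                         result$loadings[components, , drop = FALSE])
    xhat_keep <- input$mu + input$sigma * zhat
    p_total <- input$n_time * 12L
    x <- numeric(p_total)
    keep <- setdiff(seq_len(p_total), input$dropped)
    x[keep] <- xhat_keep
    if (length(input$dropped)) {
      # constant variables reconstruct as their (constant) raw value
      x[input$dropped] <- colMeans(input$raw)[input$dropped]
    }
    matrix(x, input$n_time, 12L, dimnames = list(NULL, channel_names()))
  }
  if (!is.null(groups)) {
    groups <- as.character(groups)
    out <- lapply(sort(unique(groups)), function(g) {
      rebuild(colMeans(result$scores[groups == g, components, drop = FALSE]))
    })
    names(out) <- sort(unique(groups))
    out
  } else {
    if (is.null(scores)) stop("either scores or groups must be supplied")
    rebuild(scores)
  }
}

#' Leave-one-out surrogate PCA validation
#'
#' Refits the standardization and PCA once per left-out participant
#' (n surrogate fits on (n-1) x p matrices), matches each surrogate's
#' components to the full-fit target component by maximal absolute
#' loading correlation (sign-aligned), re-runs the group t-test on the
#' matched surrogate scores, and classifies each surrogate as significant
#' (p < 0.05), marginal (0.05 <= p < 0.10), or non-significant. Matches
#' whose two best candidates lie within 0.01 in |correlation| are flagged
#' ambiguous and both candidates are reported.
#'
#' @param input a [assemble_and_standardize()] result.
#' @param groups group label per participant.
#' @param target_loading loading vector of the full-fit target component
#'   (length = number of retained variables of `input`).
#' @param variance_threshold retention threshold for the surrogate fits.
#' @param var_equal pooled or Welch t-tests (see [test_group_scores()]).
#' @return list with `table` (data.frame `left_out, matched_component,
#'   loading_cor, retained, t, p, class, ambiguous, runner_up`) and
#'   `counts` (significant / marginal / non-significant totals).
#' @export
loo_surrogate_validation <- function(input, groups, target_loading,
                                     variance_threshold = 0.90,
                                     var_equal = TRUE) {
  stopifnot(inherits(input, "pca_input"))
  n <- nrow(input$raw)
  if (n < 4L) stop("insufficient data: leave-one-out needs >= 4 participants")
  groups <- as.character(groups)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    Xi <- input$raw[-i, , drop = FALSE]
    mu <- colMeans(Xi)
    sigma <- apply(Xi, 2L, stats::sd)
    keep <- which(sigma >= 1e-12)
    Zi <- sweep(sweep(Xi[, keep, drop = FALSE], 2L, mu[keep]), 2L,
                sigma[keep], `/`)
    fit <- fit_pca(Zi, variance_threshold, groups = groups[-i])
    # express the target loading over all raw variables (zeros where the
    # full fit had dropped constant columns), then compare on this
    # surrogate's retained columns
    tgt <- target_loading
    if (length(tgt) == ncol(input$z)) {
      tgt_full <- numeric(ncol(input$raw))
      tgt_full[setdiff(seq_len(ncol(input$raw)), input$dropped)] <- tgt
    } else if (length(tgt) == ncol(input$raw)) {
      tgt_full <- tgt
    } else stop("target_loading length does not match the input variables")
    cors <- abs(stats::cor(t(fit$loadings), tgt_full[keep]))
    ord <- order(cors, decreasing = TRUE)
    best <- ord[1L]
    ambiguous <- length(ord) > 1L && (cors[best] - cors[ord[2L]]) < 0.01
    sc <- fit$scores[, best]
    if (stats::cor(fit$loadings[best, ], tgt_full[keep]) < 0) sc <- -sc
    lv <- sort(unique(groups[-i]))
    tt <- stats::t.test(sc[groups[-i] == lv[1]], sc[groups[-i] == lv[2]],
                        var.equal = var_equal)
    p <- tt$p.value
    rows[[i]] <- data.frame(
      left_out = i, matched_component = best,
      loading_cor = cors[best], retained = best <= fit$retained_k,
      t = unname(tt$statistic), p = p,
      class = if (p < 0.05) "significant" else if (p < 0.10) "marginal"
              else "non-significant",
      ambiguous = ambiguous,
      runner_up = if (ambiguous) ord[2L] else NA_integer_)
  }
  tab <- do.call(rbind, rows)
  counts <- c(significant = sum(tab$class == "significant"),
              marginal = sum(tab$class == "marginal"),
              `non-significant` = sum(tab$class == "non-significant"))
  list(table = tab, counts = counts)
}

#' Correlate component scores with a balance metric
#'
#' Pearson correlation of one component's scores against a per-participant
#' balance metric (e.g. sway-amplitude variability), overall and within
#' each group.
#'
#' @param scores numeric score vector (one component).
#' @param metric numeric balance metric, same participants.
#' @param groups optional group labels for within-group correlations.
#' @return data.frame `scope, n, r, p`.
#' @export
correlate_scores_with_balance <- function(scores, metric, groups = NULL) {
  if (length(scores) != length(metric)) stop("paired vectors required")
  if (anyNA(scores) || anyNA(metric)) stop("missing values are not allowed")
  if (length(scores) < 3L) stop("need >= 3 participants")
  one <- function(s, m, label) {
    if (stats::sd(s) == 0 || stats::sd(m) == 0) {
      stop("undefined correlation: zero variance in ", label)
    }
    ct <- stats::cor.test(s, m)
    data.frame(scope = label, n = length(s),
               r = unname(ct$estimate), p = ct$p.value)
  }
  out <- one(scores, metric, "all")
  if (!is.null(groups)) {
    groups <- as.character(groups)
    for (g in sort(unique(groups))) {
      sel <- groups == g
      out <- rbind(out, one(scores[sel], metric[sel], g))
    }
  }
  rownames(out) <- NULL
  out
}
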