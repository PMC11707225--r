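#' Cohen's d with pooled standard deviation
#'
#' `(mean(b) - mean(a)) / s_pooled`, pooling variances with `n - 1`
#' weights. Invariant to rescaling both groups by a common positive
#' factor.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return the effect size.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs >= 2 values")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) stop("undefined effect: zero pooled SD")
  (mean(b) - mean(a)) / sqrt(sp2)
}

#' Mixed 2 x 2 ANOVA with partial eta squared
#'
#' Two-way repeated-measures ANOVA with one between-subjects factor
#' (group) and one within-subjects factor (condition), on one observation
#' per participant per condition. Effects are tested against their own
#' stratum error terms (subjects within groups for the group effect; the
#' condition-by-subjects residual for condition and the interaction), and
#' partial eta squared is `SS_effect / (SS_effect + SS_error)` with each
#' effect's own error. Bonferroni post hoc comparisons (m = 2 per family)
#' contrast groups within each condition (independent t) and conditions
#' within each group (paired t), with 95% CIs of the differences.
#' Normality of the cell data is the caller's responsibility (see
#' [normality_check()]).
#'
#' @param data data.frame with one row per participant x condition.
#' @param value,participant,group,condition column names in `data`.
#' @return an object of class `mixed_anova`: `effects` (data.frame
#'   `effect, df1, df2, F, p, pes`), `posthoc`, `cells` (mean and SD per
#'   group x condition).
#' @export
mixed_anova_2x2 <- function(data, value = "value",
                            participant = "participant", group = "group",
                            condition = "condition") {
  d <- data.frame(y = data[[value]],
                  id = factor(data[[participant]]),
                  g = factor(data[[group]]),
                  c = factor(data[[condition]]))
  if (anyNA(d)) stop("design error: missing values")
  if (nlevels(d$g) != 2L || nlevels(d$c) != 2L) {
    stop("design error: need exactly 2 groups and 2 conditions")
  }
  counts <- table(d$id, d$c)
  if (any(counts != 1L)) {
    stop("design error: every participant needs exactly one value per condition")
  }
  fit <- stats::aov(y ~ g * c + Error(id), data = d)
  s <- summary(fit)
  between <- s[["Error: id"]][[1L]]
  within <- s[["Error: Within"]][[1L]]
  pick <- function(tab, name) {
    i <- match(name, trimws(rownames(tab)))
    if (is.na(i)) stop("ANOVA term not found: ", name)
    tab[i, , drop = FALSE]
  }
  ss_err_b <- pick(between, "Residuals")[["Sum Sq"]]
  ss_err_w <- pick(within, "Residuals")[["Sum Sq"]]
  eff <- function(tab, name, ss_err) {
    r <- pick(tab, name)
    data.frame(effect = name, df1 = r[["Df"]],
               df2 = pick(tab, "Residuals")[["Df"]],
               F = r[["F value"]], p = r[["Pr(>F)"]],
               pes = r[["Sum Sq"]] / (r[["Sum Sq"]] + ss_err))
  }
  effects <- rbind(eff(between, "g", ss_err_b),
                   eff(within, "c", ss_err_w),
                   eff(within, "g:c", ss_err_w))
  effects$effect <- c("group", "condition", "group:condition")

  # Bonferroni post hocs, m = 2 per family
  ph <- list()
  for (cc in levels(d$c)) {
    sub <- d[d$c == cc, ]
    tt <- stats::t.test(y ~ g, data = sub, var.equal = TRUE)
    ph[[length(ph) + 1L]] <- data.frame(
      family = "group within condition", level = cc,
      comparison = paste(levels(d$g), collapse = " - "),
      estimate = unname(diff(rev(tt$estimate))),
      ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
      p_raw = tt$p.value, p_adj = min(1, 2 * tt$p.value))
  }
  wide <- stats::reshape(d, idvar = "id", timevar = "c", direction = "wide")
  cl <- levels(d$c)
  for (gg in levels(d$g)) {
    sel <- wide[[paste0("g.", cl[1])]] == gg
    x1 <- wide[[paste0("y.", cl[1])]][sel]
    x2 <- wide[[paste0("y.", cl[2])]][sel]
    tt <- stats::t.test(x1, x2, paired = TRUE)
    ph[[length(ph) + 1L]] <- data.frame(
      family = "condition within group", level = gg,
      comparison = paste(cl, collapse = " - "),
      estimate = unname(tt$estimate),
      ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
      p_raw = tt$p.value, p_adj = min(1, 2 * tt$p.value))
  }
  cells <- stats::aggregate(y ~ g + c, data = d,
                            FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  cells <- data.frame(group = cells$g, condition = cells$c,
                      mean = cells$y[, "mean"], sd = cells$y[, "sd"])
  structure(list(effects = effects, posthoc = do.call(rbind, ph),
                 cells = cells),
            class = "mixed_anova")
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat("mixed 2x2 ANOVA\n")
  print(x$effects, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Stepwise multiple linear regression (p-value criterion)
#'
#' Forward selection with backward removal: at each step the candidate
#' with the smallest partial-F p value enters if `p < p_enter`; after
#' each entry, any included predictor whose p value exceeds `p_remove` is
#' removed (largest first). Reports the cumulative R-squared ladder at
#' each entry and the final coefficients with 95% CIs.
#'
#' @param y outcome vector.
#' @param X candidate predictor matrix or data.frame (named columns).
#' @param p_enter,p_remove entry / removal thresholds (defaults 0.05 and
#'   0.10).
#' @return an object of class `stepwise_model`: `steps` (data.frame
#'   `step, action, predictor, r_squared, p`), `selected`,
#'   `coefficients` (term, beta, ci_lo, ci_hi, p), `r_squared`,
#'   `f_statistic` (`F, df1, df2, p`), `model` (the final `lm`).
#' @export
stepwise_regression <- function(y, X, p_enter = 0.05, p_remove = 0.10) {
  X <- as.data.frame(X)
  if (is.null(names(X)) || any(!nzchar(names(X)))) stop("X needs named columns")
  if (anyNA(y) || anyNA(X)) stop("missing values are not allowed")
  n <- length(y)
  if (nrow(X) != n) stop("y and X sizes differ")
  dat <- data.frame(.y = y, X, check.names = FALSE)
  included <- character(0)
  steps <- list()
  fit_for <- function(vars) {
    fml <- if (length(vars)) {
      stats::reformulate(sprintf("`%s`", vars), response = ".y")
    } else .y ~ 1
    stats::lm(fml, data = dat)
  }
  coef_p <- function(fit) {
    cf <- summary(fit)$coefficients
    p <- cf[-1L, 4L]
    names(p) <- gsub("`", "", rownames(cf)[-1L])
    p
  }
  repeat {
    cands <- setdiff(names(X), included)
    if (!length(cands) || length(included) >= n - 2L) break
    pvals <- vapply(cands, function(v) {
      fit <- fit_for(c(included, v))
      cf <- stats::coef(fit)
      if (anyNA(cf)) {
        stop("collinearity error: ", v, " is collinear with {",
             paste(included, collapse = ", "), "}")
      }
      coef_p(fit)[[v]]
    }, numeric(1L))
    best <- names(pvals)[which.min(pvals)]
    if (pvals[[best]] >= p_enter) break
    included <- c(included, best)
    fit <- fit_for(included)
    steps[[length(steps) + 1L]] <- data.frame(
      step = length(steps) + 1L, action = "add", predictor = best,
      r_squared = summary(fit)$r.squared, p = pvals[[best]])
    repeat {
      p_in <- coef_p(fit_for(included))
      worst <- names(p_in)[which.max(p_in)]
      if (p_in[[worst]] <= p_remove) break
      included <- setdiff(included, worst)
      fit <- fit_for(included)
      steps[[length(steps) + 1L]] <- data.frame(
        step = length(steps) + 1L, action = "remove", predictor = worst,
        r_squared = summary(fit)$r.squared, p = p_in[[worst]])
    }
  }
  final <- fit_for(included)
  sm <- summary(final)
  coefs <- if (length(included)) {
    ci <- stats::confint(final)
    cf <- sm$coefficients
    data.frame(term = gsub("`", "", rownames(cf)),
               beta = cf[, 1L], ci_lo = ci[, 1L], ci_hi = ci[, 2L],
               p = cf[, 4L], row.names = NULL)
  } else data.frame(term = "(Intercept)", beta = mean(y),
                    ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_)
  fstat <- if (!is.null(sm$fstatistic)) {
    data.frame(F = unname(sm$fstatistic[1L]),
               df1 = unname(sm$fstatistic[2L]),
               df2 = unname(sm$fstatistic[3L]),
               p = stats::pf(sm$fstatistic[1L], sm$fstatistic[2L],
                             sm$fstatistic[3L], lower.tail = FALSE))
  } else data.frame(F = NA_real_, df1 = NA_real_, df2 = NA_real_,
                    p = NA_real_)
  structure(list(steps = if (length(steps)) do.call(rbind, steps) else
                   data.frame(step = integer(0), action = character(0),
                              predictor = character(0),
                              r_squared = numeric(0), p = numeric(0)),
                 selected = included, coefficients = coefs,
                 r_squared = sm$r.squared, f_statistic = fstat,
                 p_enter = p_enter, p_remove = p_remove, model = final),
            class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat("stepwise regression (p_enter =", x$p_enter,
      ", p_remove =", x$p_remove, ")\n")
  if (nrow(x$steps)) print(x$steps, row.names = FALSE, digits = 4)
  else cat("no predictor entered\n")
  invisible(x)
}

#' Shapiro-Wilk normality diagnostic
#'
#' Convenience wrapper reporting the Shapiro-Wilk statistic per cell of a
#' grouping; purely diagnostic, it never gates any computation.
#'
#' @param x numeric vector.
#' @param by optional grouping vector.
#' @return data.frame `scope, W, p`.
#' @export
normality_check <- function(x, by = NULL) {
  one <- function(v, label) {
    st <- stats::shapiro.test(v)
    data.frame(scope = label, W = unname(st$statistic), p = st$p.value)
  }
  if (is.null(by)) return(one(x, "all"))
  out <- do.call(rbind, lapply(sort(unique(as.character(by))), function(g) {
    one(x[by == g], g)
  }))
  rownames(out) <- NULL
  out
}
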