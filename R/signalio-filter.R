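#' Multichannel time-series block
#'
#' @param samples T x C numeric matrix (time in rows) or a numeric vector.
#' @param sample_rate sampling rate, Hz.
#' @param start_time time of the first sample, seconds.
#' @return an object of class `ts_block` (matrix with attributes).
#' @export
ts_block <- function(samples, sample_rate, start_time = 0) {
  samples <- as.matrix(samples)
  if (!is.numeric(sample_rate) || sample_rate <= 0) stop("sample_rate must be > 0")
  if (anyNA(samples)) stop("ts_block may not contain missing values")
  structure(samples, sample_rate = sample_rate, start_time = start_time,
            class = "ts_block")
}

# zero-phase one-channel filter: odd-reflection padding at both ends plus
# steady-state initial conditions, forward and backward passes
filtfilt_refl <- function(b, a, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  one_pass <- function(v) {
    head_pad <- 2 * v[1] - v[seq(pad + 1L, 2L)]
    tail_pad <- 2 * v[length(v)] - v[seq(length(v) - 1L, length(v) - pad)]
    ext <- c(head_pad, v, tail_pad)
    k <- max(length(a), length(b)) - 1L
    y <- signal::filter(b, a, ext,
                        init.x = rep(ext[1], k), init.y = rep(ext[1], k))
    y[seq(pad + 1L, pad + length(v))]
  }
  rev(one_pass(rev(one_pass(x))))
}

#' Zero-phase low-pass Butterworth filter
#'
#' Fourth-order, 10 Hz by default, applied forward and backward
#' (dual-pass) so the output is phase-free; DC gain is 1 and the length is
#' preserved. Edge transients are suppressed by odd-reflection padding
#' with steady-state filter initialisation. No cutoff correction is
#' applied for the dual pass.
#'
#' @param block a [ts_block()], matrix, or numeric vector.
#' @param cutoff low-pass cutoff, Hz; must be below the Nyquist rate.
#' @param order filter order of each pass.
#' @param sample_rate required when `block` carries no rate attribute.
#' @return object of the same shape as `block`.
#' @export
butterworth_lowpass <- function(block, cutoff = 10, order = 4,
                                sample_rate = NULL) {
  rate <- attr(block, "sample_rate") %||% sample_rate
  if (is.null(rate)) stop("sample_rate must be supplied")
  if (cutoff >= rate / 2) stop("invalid filter: cutoff must be below the Nyquist rate")
  if (cutoff <= 0) stop("invalid filter: cutoff must be > 0")
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  pad <- ceiling(3 * rate / cutoff)
  apply_cols(block, function(x) filtfilt_refl(bf$b, bf$a, x, pad))
}

#' Cubic-spline downsampling
#'
#' Resamples every channel onto the target time grid aligned at the block
#' start by cubic-spline interpolation (exact on polynomials up to cubic).
#' The output length is `round(duration * target_rate)` with
#' `duration = n / source_rate`.
#'
#' @param block a [ts_block()], matrix, or numeric vector.
#' @param target_rate target sampling rate, Hz; must not exceed the
#'   source rate.
#' @param sample_rate source rate when `block` carries no rate attribute.
#' @return resampled object with updated `sample_rate` attribute.
#' @export
spline_downsample <- function(block, target_rate = 100, sample_rate = NULL) {
  rate <- attr(block, "sample_rate") %||% sample_rate
  if (is.null(rate)) stop("sample_rate must be supplied")
  if (target_rate > rate) stop("invalid resample: target rate above source rate")
  if (target_rate == rate) return(block)
  n <- if (is.matrix(block)) nrow(block) else length(block)
  t_old <- (seq_len(n) - 1) / rate
  m <- round(n / rate * target_rate)
  t_new <- (seq_len(m) - 1) / target_rate
  out <- apply_cols(block, function(x) {
    stats::spline(t_old, x, xout = t_new, method = "fmm")$y
  })
  attr(out, "sample_rate") <- target_rate
  out
}

# apply a vector function column-wise, preserving class and attributes
apply_cols <- function(block, f) {
  if (is.matrix(block)) {
    out <- block
    for (j in seq_len(ncol(block))) {
      y <- f(as.numeric(unclass(block)[, j]))
      if (length(y) != nrow(out)) {
        if (j == 1L) {
          out2 <- matrix(0, length(y), ncol(block),
                         dimnames = list(NULL, colnames(block)))
          attrs <- attributes(block)
          attrs$dim <- NULL
          attrs$dimnames <- NULL
          for (nm in names(attrs)) attr(out2, nm) <- attrs[[nm]]
          out <- out2
        }
      }
      out[, j] <- y
    }
    out
  } else {
    y <- f(as.numeric(block))
    attributes(y) <- attributes(block)[setdiff(names(attributes(block)), "names")]
    y
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trim a trial to its analysed 10-second middle window
#'
#' Moving-platform trials are anchored on the platform's zero crossing
#' moving medially (toward the stance-foot's body midline: negative lab X
#' for a right stance, positive for left) nearest to the trial centre;
#' static trials take the centred window. The window spans exactly
#' `round(window_s * sample_rate)` samples and is returned as 0-based
#' half-open indices to be applied to all synchronised channels.
#'
#' @param n_samples trial length in samples.
#' @param sample_rate sampling rate, Hz.
#' @param platform_disp platform displacement series (metres) for moving
#'   trials; `NULL` for static trials.
#' @param side stance side, `"right"` or `"left"`.
#' @param window_s analysis window length, seconds (default 10).
#' @return an object of class `trim_window`: list with 0-based
#'   `start_index`, `end_index` (half-open).
#' @export
trim_to_middle_10s <- function(n_samples, sample_rate, platform_disp = NULL,
                               side = c("right", "left"), window_s = 10) {
  side <- match.arg(side)
  len <- round(window_s * sample_rate)
  if (n_samples < len) stop("trim error: trial shorter than the analysis window")
  if (is.null(platform_disp)) {
    start <- floor((n_samples - len) / 2)
  } else {
    if (length(platform_disp) != n_samples) {
      stop("platform series length must match the trial")
    }
    medial_sign <- if (side == "right") -1 else 1
    x <- platform_disp * medial_sign   # medial becomes positive
    # zero crossings entering the medial direction, linearly interpolated
    i <- seq_len(n_samples - 1L)
    cross <- which((x[i] < 0 & x[i + 1L] > 0) |
                     (x[i] == 0 & x[i + 1L] > 0))
    if (!length(cross)) stop("trim error: no medially directed zero crossing")
    frac <- ifelse(x[cross] == 0, 0,
                   -x[cross] / (x[cross + 1L] - x[cross]))
    t_c <- (cross - 1L) + frac         # 0-based fractional sample index
    target <- (n_samples - len) / 2
    cand <- round(t_c)
    ok <- cand >= 0 & cand + len <= n_samples
    if (!any(ok)) stop("trim error: no qualifying zero crossing leaves a full window")
    cand <- cand[ok]
    t_c <- t_c[ok]
    ord <- order(abs(t_c - target), t_c)
    start <- cand[ord[1L]]
  }
  structure(list(start_index = as.integer(start),
                 end_index = as.integer(start + len)),
            class = "trim_window")
}

#' Apply a trim window to a series
#' @param x vector, matrix, or tensor with time in rows.
#' @param window a [trim_to_middle_10s()] result.
#' @return the trimmed object.
#' @export
apply_trim <- function(x, window) {
  stopifnot(inherits(window, "trim_window"))
  idx <- seq(window$start_index + 1L, window$end_index)
  if (inherits(x, "joint_angle_tensor")) return(ja_window(x, idx))
  if (is.matrix(x)) {
    out <- unclass(x)[idx, , drop = FALSE]
    for (nm in setdiff(names(attributes(x)), c("dim", "dimnames"))) {
      attr(out, nm) <- attr(x, nm)
    }
    out
  } else {
    x[idx]
  }
}
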