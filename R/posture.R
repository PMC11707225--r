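#' Centre of pressure from force-plate data
#'
#' `COP_x = (-My - Fx * d_z) / Fz + o_x`,
#' `COP_y = ( Mx - Fy * d_z) / Fz + o_y`, where `d_z` is the offset of the
#' plate surface above the moment reference and `(o_x, o_y)` the plate
#' origin offset. Samples must be loaded: `|Fz|` at or above
#' `load_threshold`.
#'
#' @param record force-plate data.frame with columns `Fx,Fy,Fz,Mx,My,Mz`
#'   and a `sample_rate` attribute.
#' @param d_z plate surface offset, metres.
#' @param origin plate origin offset `(o_x, o_y)`, metres.
#' @param load_threshold minimum `|Fz|` in newtons (default 20).
#' @return T x 2 matrix (columns `x` mediolateral, `y` anteroposterior,
#'   metres) with attribute `sample_rate`.
#' @export
compute_cop <- function(record, d_z = 0, origin = c(0, 0),
                        load_threshold = 20) {
  need <- c("Fx", "Fy", "Fz", "Mx", "My", "Mz")
  missing <- setdiff(need, names(record))
  if (length(missing)) stop("force record lacks column(s) ",
                            paste(missing, collapse = ", "))
  fz <- record$Fz
  bad <- which(abs(fz) < load_threshold)
  if (length(bad)) {
    stop("unloaded samples (|Fz| < ", load_threshold, " N) at indices ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "")
  }
  cop <- cbind(x = (-record$My - record$Fx * d_z) / fz + origin[1],
               y = (record$Mx - record$Fy * d_z) / fz + origin[2])
  attr(cop, "sample_rate") <- attr(record, "sample_rate")
  cop
}

#' Foot boundary rectangle from the four border markers
#'
#' The foot's long axis is the trial-averaged unit vector from the
#' calcaneus to the first-distal-phalanx marker (projected to the
#' horizontal plane); the mediolateral axis is its horizontal
#' perpendicular. The rectangle is the axis-aligned bounding box of the
#' four trial-averaged marker projections in this (long-axis,
#' mediolateral) foot frame.
#'
#' @param mt1,mt5,phalanx,calcaneus T x 3 marker trajectories (metres;
#'   see [marker_xyz()]).
#' @return an object of class `foot_boundary`: origin (markers centroid),
#'   unit axes `ap_axis` and `ml_axis` (lab frame), `ap_range` and
#'   `ml_range` (metres, foot frame), `corners` (4 x 2 foot-frame
#'   coordinates).
#' @export
foot_boundary <- function(mt1, mt5, phalanx, calcaneus) {
  avg <- rbind(mt1 = colMeans(as.matrix(mt1)),
               mt5 = colMeans(as.matrix(mt5)),
               phalanx = colMeans(as.matrix(phalanx)),
               calcaneus = colMeans(as.matrix(calcaneus)))
  axis3 <- avg["phalanx", ] - avg["calcaneus", ]
  axis3[3] <- 0
  len <- sqrt(sum(axis3^2))
  if (len < 1e-6) stop("degenerate axis: calcaneus and phalanx markers coincide")
  ap <- axis3 / len
  ml <- c(ap[2], -ap[1], 0)     # horizontal perpendicular (lateral for a
                                # right foot pointing forward)
  origin <- colMeans(avg)
  rel <- sweep(avg, 2L, origin)
  coords <- cbind(ap = as.numeric(rel %*% ap), ml = as.numeric(rel %*% ml))
  structure(list(origin = origin, ap_axis = ap, ml_axis = ml,
                 ap_range = range(coords[, "ap"]),
                 ml_range = range(coords[, "ml"]),
                 corners = coords),
            class = "foot_boundary")
}

#' Express a COP trajectory in the foot frame
#'
#' @param cop T x 2 lab/support-surface COP (columns x, y, metres).
#' @param boundary a [foot_boundary()].
#' @return T x 2 matrix with columns `ml`, `ap` (metres, foot frame),
#'   `sample_rate` attribute preserved.
#' @export
cop_to_foot_frame <- function(cop, boundary) {
  stopifnot(inherits(boundary, "foot_boundary"))
  rel <- cbind(cop[, 1] - boundary$origin[1], cop[, 2] - boundary$origin[2])
  out <- cbind(ml = rel[, 1] * boundary$ml_axis[1] +
                 rel[, 2] * boundary$ml_axis[2],
               ap = rel[, 1] * boundary$ap_axis[1] +
                 rel[, 2] * boundary$ap_axis[2])
  attr(out, "sample_rate") <- attr(cop, "sample_rate")
  out
}

#' Mediolateral time-to-boundary series
#'
#' Per sample, with mediolateral COP position `p`, velocity `v` (central
#' differences of the supplied, already filtered COP), and rectangle
#' bounds `(b_lo, b_hi)`: `ttb = (b_hi - p) / v` when `v > 0`,
#' `(p - b_lo) / |v|` when `v < 0`. Near-zero velocity samples
#' (`|v| < vel_threshold`) take the cap value and are flagged invalid;
#' negative values (COP outside the rectangle) are clipped to 0 and
#' flagged `outside`. A warning is raised when more than 5% of samples
#' fall outside the rectangle.
#'
#' @param cop_ml mediolateral COP series in the foot frame (metres), or a
#'   T x 2 [cop_to_foot_frame()] matrix (its `ml` column is used).
#' @param boundary a [foot_boundary()] or a numeric `c(lo, hi)` pair of
#'   mediolateral bounds (metres).
#' @param sample_rate Hz (taken from `cop_ml` if present).
#' @param cap value assigned to invalid samples, seconds (default the
#'   10-s analysis window).
#' @param vel_threshold near-zero velocity cutoff, m/s.
#' @return an object of class `ttb_series`: `ttb` (seconds), `valid`,
#'   `outside` (logicals), `cap`, `sample_rate`.
#' @export
ttb_ml <- function(cop_ml, boundary, sample_rate = NULL, cap = 10,
                   vel_threshold = 1e-6) {
  rate <- attr(cop_ml, "sample_rate") %||% sample_rate
  if (is.null(rate)) stop("sample_rate must be supplied")
  p <- if (is.matrix(cop_ml)) cop_ml[, "ml"] else as.numeric(cop_ml)
  bounds <- if (inherits(boundary, "foot_boundary")) boundary$ml_range
            else sort(as.numeric(boundary))
  v <- deriv_central(p, rate)
  ttb <- rep(cap, length(p))
  valid <- abs(v) >= vel_threshold
  up <- valid & v > 0
  dn <- valid & v < 0
  ttb[up] <- (bounds[2] - p[up]) / v[up]
  ttb[dn] <- (p[dn] - bounds[1]) / abs(v[dn])
  outside <- valid & ttb < 0
  ttb[outside] <- 0
  if (mean(p < bounds[1] | p > bounds[2]) > 0.05) {
    warning("boundary mismatch: COP outside the foot rectangle for > 5% of samples")
  }
  structure(list(ttb = ttb, valid = valid, outside = outside,
                 cap = cap, sample_rate = rate),
            class = "ttb_series")
}

#' Minima-based time-to-boundary summary
#'
#' Local minima are valid samples strictly lower than both neighbouring
#' (distinct) values; plateaus contribute their first sample; run
#' endpoints adjacent to invalid samples are not minima. The summary
#' reports the mean and sample SD over the local minima and the absolute
#' (global) minimum over all valid samples. A trial without any interior
#' local minimum is flagged degenerate (mean and SD are `NA`).
#'
#' @param series a [ttb_ml()] result.
#' @return an object of class `ttb_summary`: `mean_of_minima`,
#'   `absolute_minimum`, `sd_of_minima` (seconds), `n_minima`,
#'   `degenerate`.
#' @export
ttb_summary <- function(series) {
  stopifnot(inherits(series, "ttb_series"))
  if (!any(series$valid)) stop("degenerate trial: no valid samples")
  minima <- numeric(0)
  runs <- rle(series$valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in which(runs$values)) {
    x <- series$ttb[starts[r]:ends[r]]
    rv <- rle(x)
    if (length(rv$values) >= 3L) {
      i <- 2:(length(rv$values) - 1L)
      is_min <- rv$values[i] < rv$values[i - 1L] & rv$values[i] < rv$values[i + 1L]
      minima <- c(minima, rv$values[i][is_min])
    }
  }
  n_min <- length(minima)
  structure(list(
    mean_of_minima = if (n_min) mean(minima) else NA_real_,
    absolute_minimum = min(series$ttb[series$valid]),
    sd_of_minima = if (n_min >= 2L) stats::sd(minima) else NA_real_,
    n_minima = n_min,
    degenerate = n_min == 0L
  ), class = "ttb_summary")
}

#' Centre-of-pressure sway summary
#'
#' `sd_amp` is the sample SD of the COP distance from the trajectory
#' centre (the mean position); `sway_velocity` is the COP path length
#' divided by the traversed duration `(n - 1) / rate`.
#'
#' @param cop T x 2 COP matrix (metres).
#' @param sample_rate Hz (taken from `cop` if present).
#' @return list with `sd_amp` (metres) and `sway_velocity` (m/s).
#' @export
sway_summary <- function(cop, sample_rate = NULL) {
  rate <- attr(cop, "sample_rate") %||% sample_rate
  if (is.null(rate)) stop("sample_rate must be supplied")
  cop <- as.matrix(cop)
  if (nrow(cop) < 2L) stop("need >= 2 samples")
  centre <- colMeans(cop)
  amp <- sqrt((cop[, 1] - centre[1])^2 + (cop[, 2] - centre[2])^2)
  steps <- sqrt(diff(cop[, 1])^2 + diff(cop[, 2])^2)
  list(sd_amp = stats::sd(amp),
       sway_velocity = sum(steps) / ((nrow(cop) - 1) / rate))
}
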