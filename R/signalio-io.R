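#' Write a marker set as a TRC file
#'
#' Standard tab-separated TRC layout (header with DataRate, NumFrames,
#' NumMarkers, Units) with positions in millimetres.
#'
#' @param markers a [marker_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trc <- function(markers, path) {
  stopifnot(inherits(markers, "marker_set"))
  labels <- attr(markers, "labels")
  rate <- attr(markers, "sample_rate")
  n <- nrow(markers)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
  writeLines(paste("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                   "Units", "OrigDataRate", "OrigDataStartFrame",
                   "OrigNumFrames", sep = "\t"), con)
  writeLines(sprintf("%g\t%g\t%d\t%d\tmm\t%g\t1\t%d",
                     rate, rate, n, length(labels), rate, n), con)
  head1 <- c("Frame#", "Time",
             unlist(lapply(labels, function(l) c(l, "", ""))))
  writeLines(paste(head1, collapse = "\t"), con)
  head2 <- c("", "", unlist(lapply(seq_along(labels), function(i) {
    paste0(c("X", "Y", "Z"), i)
  })))
  writeLines(paste(head2, collapse = "\t"), con)
  writeLines("", con)
  tt <- (seq_len(n) - 1) / rate
  dat <- cbind(seq_len(n), tt, unclass(markers) * 1000)
  lines <- apply(dat, 1L, function(r) {
    paste(c(sprintf("%d", r[1]), sprintf("%.6f", r[2]),
            sprintf("%.6f", r[-(1:2)])), collapse = "\t")
  })
  writeLines(lines, con)
  invisible(path)
}

#' Read a TRC marker file
#'
#' Positions are converted to metres regardless of the on-disk unit
#' (mm or m per the Units header field); labels are preserved and the
#' sampling rate is taken from the header.
#'
#' @param path TRC file.
#' @return a [marker_set()].
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6L) stop("format error: truncated TRC file ", path)
  hdr_names <- strsplit(lines[2], "\t")[[1]]
  hdr_vals <- strsplit(lines[3], "\t")[[1]]
  if (length(hdr_vals) < length(hdr_names)) {
    stop("format error at line 3: incomplete TRC header")
  }
  hdr <- stats::setNames(as.list(hdr_vals), hdr_names)
  if (is.null(hdr$Units)) stop("format error: Units header missing")
  unit_scale <- switch(hdr$Units, mm = 1e-3, m = 1,
                       stop("format error: unknown TRC unit ", hdr$Units))
  rate <- as.numeric(hdr$DataRate)
  n_markers <- as.integer(hdr$NumMarkers)
  lab_row <- strsplit(lines[4], "\t")[[1]]
  labels <- lab_row[-(1:2)]
  labels <- labels[labels != ""]
  if (length(labels) != n_markers) {
    stop("format error at line 4: expected ", n_markers, " marker labels")
  }
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  ncol_expect <- 2L + 3L * n_markers
  rows <- strsplit(data_lines, "\t")
  bad <- which(vapply(rows, length, 1L) != ncol_expect)
  if (length(bad)) {
    stop("format error at line ", 5L + bad[1L] +
           sum(!nzchar(trimws(lines[-(1:5)]))[seq_len(bad[1L])]),
         ": ragged TRC data row")
  }
  mat <- matrix(as.numeric(unlist(rows)), ncol = ncol_expect, byrow = TRUE)
  pos <- mat[, -(1:2), drop = FALSE] * unit_scale
  colnames(pos) <- paste(rep(labels, each = 3L), c("X", "Y", "Z"), sep = "_")
  marker_set(pos, sample_rate = rate)
}

#' Write a marker set as a labelled wide CSV
#'
#' Columns `time` then `<marker>_X/_Y/_Z` in metres.
#' @param markers a [marker_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_marker_csv <- function(markers, path) {
  stopifnot(inherits(markers, "marker_set"))
  rate <- attr(markers, "sample_rate")
  df <- data.frame(time = (seq_len(nrow(markers)) - 1) / rate,
                   unclass(markers), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a labelled wide marker CSV
#'
#' Expects a `time` column plus `<marker>_X/_Y/_Z` columns in metres.
#' Missing cells are recorded as gaps and spline-filled when no gap on a
#' marker coordinate exceeds `max_gap` consecutive frames; longer gaps
#' (or gaps touching the trial ends) are a hard error.
#'
#' @param path CSV file.
#' @param max_gap longest fillable gap, frames.
#' @return a [marker_set()] with attribute `gaps` (filled-sample count
#'   per column).
#' @export
read_marker_csv <- function(path, max_gap = 10) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("format error: empty marker CSV ", path)
  if (!"time" %in% names(df)) stop("format error: marker CSV needs a time column")
  tt <- df$time
  rate <- 1 / stats::median(diff(tt))
  pos <- as.matrix(df[setdiff(names(df), "time")])
  filled <- fill_marker_gaps(pos, max_gap = max_gap)
  marker_set(filled, sample_rate = rate)
}

# spline-fill short NA runs per column; error on long or edge gaps
fill_marker_gaps <- function(pos, max_gap = 10) {
  gaps <- integer(ncol(pos))
  for (j in seq_len(ncol(pos))) {
    x <- pos[, j]
    na <- is.na(x)
    if (!any(na)) next
    r <- rle(na)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    if (any(r$lengths[runs] > max_gap)) {
      stop("gap error: marker column ", colnames(pos)[j],
           " has more than ", max_gap, " consecutive missing frames")
    }
    if (na[1L] || na[length(x)]) {
      stop("gap error: marker column ", colnames(pos)[j],
           " is missing at the trial boundary")
    }
    idx <- which(!na)
    pos[na, j] <- stats::spline(idx, x[idx], xout = which(na),
                                method = "fmm")$y
    gaps[j] <- sum(na)
  }
  attr(pos, "gaps") <- gaps
  pos
}

#' Read marker data by dialect
#'
#' @param path file path.
#' @param dialect `"trc"` or `"wide_csv"`.
#' @param ... passed to the dialect reader.
#' @return a [marker_set()].
#' @export
read_markers <- function(path, dialect = c("trc", "wide_csv"), ...) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("format error: no such file ", path)
  switch(dialect, trc = read_trc(path), wide_csv = read_marker_csv(path, ...))
}

#' Write / read a force-plate CSV
#'
#' Columns `t,Fx,Fy,Fz,Mx,My,Mz` (seconds, N, N m).
#' @param record force-plate data.frame with `sample_rate` attribute.
#' @param path file path.
#' @return `path` / the record.
#' @export
write_force_csv <- function(record, path) {
  utils::write.csv(record[c("t", "Fx", "Fy", "Fz", "Mx", "My", "Mz")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_force_csv
#' @export
read_force_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", "Fx", "Fy", "Fz", "Mx", "My", "Mz")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("format error: force CSV lacks column(s) ",
         paste(missing, collapse = ", "))
  }
  attr(df, "sample_rate") <- 1 / stats::median(diff(df$t))
  df
}

#' Write a cohort to disk
#'
#' Serialises every trial (markers as TRC, forces as CSV) plus a manifest
#' CSV with columns
#' `participant,group,condition,side,trial,path_markers,path_forces`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- cohort$manifest
  m$path_markers <- NA_character_
  m$path_forces <- NA_character_
  for (i in seq_len(nrow(m))) {
    tr <- cohort$trials[[m$trial_id[i]]]
    if (!is.null(tr$markers)) {
      p <- file.path(dir, paste0(m$trial_id[i], ".trc"))
      write_trc(tr$markers, p)
      m$path_markers[i] <- p
    }
    if (!is.null(tr$forces)) {
      p <- file.path(dir, paste0(m$trial_id[i], "_forces.csv"))
      write_force_csv(tr$forces, p)
      m$path_forces[i] <- p
    }
  }
  utils::write.csv(m[c("participant", "group", "condition", "side", "trial",
                       "path_markers", "path_forces")],
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(m)
}

#' Read a cohort generation config
#'
#' YAML key-value config with optional sections `platform` (arguments of
#' [platform_spec()]), `effects` ([group_effect_spec()] scalars),
#' `n_per_group`, and `seed`.
#'
#' @param path YAML file.
#' @return list with `platform`, `effects`, `n_per_group`, `seed`.
#' @export
read_cohort_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read configs")
  }
  cfg <- yaml::read_yaml(path)
  platform <- do.call(platform_spec, cfg$platform %||% list())
  effects <- do.call(group_effect_spec, cfg$effects %||% list())
  list(platform = platform, effects = effects,
       n_per_group = cfg$n_per_group %||% 23,
       seed = cfg$seed %||% 1L)
}
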