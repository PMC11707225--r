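#' Platform motion specification
#'
#' Describes the mediolateral sinusoidal support-surface perturbation:
#' 1.6 Hz with 20 mm peak-to-peak displacement by default, sampled at the
#' motion-capture rate. With `phase_origin = 0` the displacement starts at
#' a zero crossing moving laterally (+X) for a right-foot stance, so the
#' medially directed zero crossings used as trimming anchors are well
#' defined.
#'
#' @param frequency oscillation frequency in Hz.
#' @param peak_to_peak peak-to-peak displacement in metres.
#' @param duration trial length in seconds.
#' @param sample_rate sampling rate in Hz.
#' @param phase_origin phase at t = 0 in radians.
#' @return an object of class `platform_spec`.
#' @export
platform_spec <- function(frequency = 1.6, peak_to_peak = 0.020,
                          duration = 15, sample_rate = 100,
                          phase_origin = 0) {
  if (!is.numeric(frequency) || frequency <= 0) stop("invalid platform spec: frequency must be > 0")
  if (!is.numeric(peak_to_peak) || peak_to_peak < 0) stop("invalid platform spec: peak_to_peak must be >= 0")
  if (!is.numeric(duration) || duration <= 0) stop("invalid platform spec: duration must be > 0")
  if (!is.numeric(sample_rate) || sample_rate <= 0) stop("invalid platform spec: sample_rate must be > 0")
  structure(list(frequency = frequency, peak_to_peak = peak_to_peak,
                 duration = duration, sample_rate = sample_rate,
                 phase_origin = phase_origin),
            class = "platform_spec")
}

#' Generate the platform displacement series
#'
#' `x(t) = (peak_to_peak / 2) * sin(2 * pi * frequency * t + phase_origin)`
#' evaluated on the sample grid `t = 0, 1/rate, ...` of length
#' `round(duration * sample_rate)`. Displacement is signed mediolateral
#' (lab X), in metres.
#'
#' @param spec a [platform_spec()].
#' @return numeric displacement vector with attribute `sample_rate`.
#' @export
generate_platform_trajectory <- function(spec) {
  stopifnot(inherits(spec, "platform_spec"))
  n <- round(spec$duration * spec$sample_rate)
  t <- (seq_len(n) - 1) / spec$sample_rate
  x <- (spec$peak_to_peak / 2) *
    sin(2 * pi * spec$frequency * t + spec$phase_origin)
  attr(x, "sample_rate") <- spec$sample_rate
  x
}

#' Count zero crossings of a signal
#'
#' Counts sign changes between consecutive samples; an exact zero followed
#' by a non-zero sample counts as one crossing. For a sinusoid this equals
#' twice the number of full cycles in the window.
#'
#' @param x numeric series.
#' @return integer crossing count.
#' @export
count_zero_crossings <- function(x) {
  n <- length(x)
  if (n < 2L) return(0L)
  a <- x[-n]
  b <- x[-1L]
  sum(a * b < 0 | (a == 0 & b != 0))
}
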