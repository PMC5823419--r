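#' Mono audio signal container
#'
#' An `audio_signal` is a uniformly sampled mono amplitude sequence together
#' with its sample rate and a start time. Sample `i` (1-based) corresponds to
#' time `start_time + (i - 1) / sample_rate` seconds; all downstream modules
#' report times in seconds under this convention.
#'
#' @param samples numeric vector of amplitudes (dimensionless, nominally in
#'   `[-1, 1]` after [normalize_amplitude()]).
#' @param sample_rate sampling rate in Hz (positive).
#' @param start_time time of the first sample in seconds (default 0).
#' @return An object of class `audio_signal`: a list with elements
#'   `samples`, `sample_rate`, `start_time`.
#' @examples
#' s <- audio_signal(sin(2 * pi * 5 * seq(0, 1, by = 1 / 100)), 100)
#' duration(s)
#' @export
audio_signal <- function(samples, sample_rate, start_time = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 0) {
    stop("`sample_rate` must be a single positive number (Hz)")
  }
  if (anyNA(samples)) stop("`samples` must not contain NA")
  structure(
    list(samples = samples, sample_rate = sample_rate,
         start_time = as.numeric(start_time)),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %g Hz, %.3f s, range [%.4g, %.4g]>\n",
              length(x$samples), x$sample_rate, duration(x),
              if (length(x$samples)) min(x$samples) else NA,
              if (length(x$samples)) max(x$samples) else NA))
  invisible(x)
}

#' Duration of an audio signal in seconds
#' @param signal an [audio_signal()].
#' @return Duration in seconds (`n / sample_rate`).
#' @export
duration <- function(signal) {
  stopifnot(inherits(signal, "audio_signal"))
  length(signal$samples) / signal$sample_rate
}

#' Time axis of an audio signal
#' @param signal an [audio_signal()].
#' @return Numeric vector of sample times in seconds.
#' @export
time_axis <- function(signal) {
  stopifnot(inherits(signal, "audio_signal"))
  signal$start_time + (seq_along(signal$samples) - 1) / signal$sample_rate
}

#' Peak-normalize an audio signal
#'
#' Divides all samples by the maximum absolute value so that the peak
#' amplitude is exactly 1. An all-zero signal is returned unchanged; the
#' operation is idempotent.
#'
#' @param signal an [audio_signal()].
#' @return An [audio_signal()] with `max(abs(samples)) == 1` (or all zeros).
#' @export
normalize_amplitude <- function(signal) {
  stopifnot(inherits(signal, "audio_signal"))
  m <- max(abs(signal$samples), 0)
  if (m == 0) return(signal)
  audio_signal(signal$samples / m, signal$sample_rate, signal$start_time)
}

#' Downsample an audio signal
#'
#' Anti-alias filters (zero-phase Butterworth low-pass at 0.45 times the
#' target rate) and resamples by linear interpolation onto the target grid.
#' The envelope statistics downstream work at scales of 0.1-3 s, so a
#' working rate of a few kHz retains everything relevant while keeping the
#' windowed sums cheap.
#'
#' @param signal an [audio_signal()].
#' @param target_rate new sampling rate in Hz; must be positive and not
#'   exceed `signal$sample_rate`.
#' @return An [audio_signal()] at `target_rate`; duration is preserved
#'   within one output sample period.
#' @export
downsample <- function(signal, target_rate) {
  stopifnot(inherits(signal, "audio_signal"))
  fs <- signal$sample_rate
  if (!is.numeric(target_rate) || length(target_rate) != 1L ||
      target_rate <= 0 || target_rate > fs) {
    stop("`target_rate` must be in (0, sample_rate]")
  }
  if (target_rate == fs) return(signal)
  x <- signal$samples
  n_out <- max(1L, round(length(x) * target_rate / fs))
  # anti-alias only when the new Nyquist actually cuts into the band
  cutoff <- 0.45 * target_rate / (fs / 2)
  if (cutoff < 1) {
    bf <- signal::butter(8, cutoff)
    x <- signal::filtfilt(bf, x)
  }
  t_in <- (seq_along(x) - 1) / fs
  t_out <- (seq_len(n_out) - 1) / target_rate
  y <- stats::approx(t_in, x, xout = t_out, rule = 2)$y
  audio_signal(y, target_rate, signal$start_time)
}
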