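#' Pipeline configuration for breath detection
#'
#' Bundles the knobs of the whole detection pipeline. All defaults are
#' the method's standard constants.
#'
#' @param working_rate processing sample rate in Hz; input audio above
#'   this rate is downsampled (default 4000 — the method works on energy
#'   envelopes at 0.1-3 s scales, so tens of kHz are wasteful).
#' @param use_preprocess logical; apply the amplitude-contrast reduction
#'   (default `TRUE`).
#' @param preprocess a [preprocess_config()].
#' @param delta,moment_l TCW/CMW half-windows in seconds (defaults 0.8
#'   and 0.1). The default `delta` is deliberately below half a cycle:
#'   a half-cycle variance window integrates almost exactly one period
#'   of a quasi-periodic signal and goes flat, while a window of about
#'   one burst duration keeps sharp rest-phase minima (see the package
#'   vignette). [suggest_scales()] provides the half-cycle convention.
#' @param estimated_cycle_s estimated breathing-cycle length in seconds
#'   (default 4); sets the boundary-spacing floor (see
#'   `min_separation`).
#' @param normalized_cmw logical; segment on the normalized CMW
#'   (default) or the raw moment integral.
#' @param w computation-window width for CMW validation of TCW minima
#'   (default 4 s, generous enough that a rest-phase minimum is never
#'   orphaned from its cycle's CMW peak).
#' @param min_separation minimum boundary spacing in seconds; default
#'   `NULL` means `0.6 * estimated_cycle_s`, which suppresses the
#'   secondary dip inside the inspiratory pause without merging
#'   neighbouring cycles.
#' @param validation,require_breath,breath_frac,adjust_boundaries passed
#'   to [segment_cycles()].
#' @param rr_stable optional override of the stable RR (times/min).
#' @param hypo_min hypopnea lower bound in seconds (default 5).
#' @param include_hypopnea logical; count hypopneas in the AHI.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(working_rate = 4000, use_preprocess = TRUE,
                            preprocess = preprocess_config(),
                            delta = 0.8, moment_l = 0.1,
                            estimated_cycle_s = 4,
                            normalized_cmw = TRUE, w = 4,
                            min_separation = NULL,
                            validation = "centered",
                            require_breath = TRUE, breath_frac = 0.1,
                            adjust_boundaries = TRUE,
                            rr_stable = NULL,
                            hypo_min = 5, include_hypopnea = FALSE) {
  scales <- scale_params(delta, moment_l)
  if (is.null(min_separation)) min_separation <- 0.6 * estimated_cycle_s
  structure(list(working_rate = working_rate,
                 use_preprocess = isTRUE(use_preprocess),
                 preprocess = preprocess, scales = scales,
                 estimated_cycle_s = estimated_cycle_s,
                 normalized_cmw = isTRUE(normalized_cmw), w = w,
                 min_separation = min_separation,
                 validation = validation,
                 require_breath = isTRUE(require_breath),
                 breath_frac = breath_frac,
                 adjust_boundaries = isTRUE(adjust_boundaries),
                 rr_stable = rr_stable,
                 hypo_min = hypo_min,
                 include_hypopnea = isTRUE(include_hypopnea)),
            class = "pipeline_config")
}

#' Detect breathing cycles and apnea events in a recording
#'
#' The full pipeline: downsample to the working rate, peak-normalize,
#' optionally reduce the amplitude contrast ([preprocess()]), compute the
#' time characteristic waveform ([tcw()]) and characteristic moment
#' waveform ([cmw()]), place breath-cycle segment points at TCW minima
#' validated by prominent CMW maxima ([segment_cycles()]), count cycles
#' per minute as the RR series, and derive the apnea report
#' ([apnea_report()]) when at least one full minute of breathing was
#' observed.
#'
#' @param signal an [audio_signal()] (e.g. from [read_wav()] or
#'   [generate_breathing()]).
#' @param config a [pipeline_config()].
#' @param keep_waveforms logical; keep the TCW/CMW traces and the
#'   processed signal in the result (needed by `plot()`; costs memory on
#'   long recordings).
#' @return An object of class `cmw_detection`: list with `segmentation`
#'   (a `segmentation_result`), `report` (an `apnea_report` or `NULL`),
#'   `scales`, `config`, `duration_s`, `sample_rate`, and (if kept)
#'   `processed`, `tcw`, `cmw`.
#' @examples
#' sim <- generate_breathing(synth_spec(duration_s = 70, seed = 7))
#' det <- cmw_detect(sim$signal,
#'                   pipeline_config(estimated_cycle_s = 4))
#' det
#' @export
cmw_detect <- function(signal, config = pipeline_config(),
                       keep_waveforms = TRUE) {
  stopifnot(inherits(signal, "audio_signal"),
            inherits(config, "pipeline_config"))
  if (signal$sample_rate > config$working_rate) {
    signal <- downsample(signal, config$working_rate)
  }
  signal <- normalize_amplitude(signal)
  proc <- if (config$use_preprocess) preprocess(signal, config$preprocess)
          else signal
  scales <- config$scales
  tc <- tcw(proc, scales)
  cm <- cmw(tc, scales, normalized = config$normalized_cmw)
  seg <- segment_cycles(tc, cm, scales, w = config$w,
                        min_separation = config$min_separation,
                        validation = config$validation,
                        require_breath = config$require_breath,
                        breath_frac = config$breath_frac,
                        adjust_boundaries = config$adjust_boundaries)
  report <- NULL
  rr_nz <- as.numeric(seg$rr_series)
  if (length(seg$boundaries) >= 2L &&
      (any(rr_nz > 0) || !is.null(config$rr_stable))) {
    report <- apnea_report(seg, rr_stable = config$rr_stable,
                           hypo_min = config$hypo_min,
                           include_hypopnea = config$include_hypopnea)
  } else if (length(seg$boundaries) < 2L) {
    warning("too few boundaries for an apnea report")
  }
  out <- list(segmentation = seg, report = report, scales = scales,
              config = config, duration_s = duration(signal),
              sample_rate = signal$sample_rate)
  if (keep_waveforms) {
    out$processed <- proc
    out$tcw <- tc
    out$cmw <- cm
  }
  structure(out, class = "cmw_detection")
}

#' @export
print.cmw_detection <- function(x, ...) {
  cat(sprintf("Breath detection over %.1f s @ %g Hz (delta = %g s, l = %g s)\n",
              x$duration_s, x$sample_rate, x$scales$delta, x$scales$moment_l))
  cat(sprintf("  %d breath cycles; RR per minute: %s\n",
              length(x$segmentation$boundaries),
              paste(as.vector(x$segmentation$rr_series), collapse = " ")))
  if (!is.null(x$report)) {
    cat(sprintf("  RR_stable %.1f/min, T_RR %.2f/min, AHI %.1f (%s)\n",
                x$report$rr_stable, x$report$t_rr, x$report$ahi,
                x$report$severity))
  }
  invisible(x)
}

#' @export
summary.cmw_detection <- function(object, ...) {
  print(object)
  seg <- object$segmentation
  if (length(seg$dd)) {
    cat("  inter-cycle intervals dd(i) [s]:\n")
    print(summary(seg$dd))
  }
  if (!is.null(object$report) && nrow(object$report$events)) {
    cat("  events:\n")
    print(object$report$events, row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.cmw_detection <- function(x, max_points = 20000L, ...) {
  if (is.null(x$tcw)) {
    stop("waveforms were not kept; rerun cmw_detect() with keep_waveforms = TRUE")
  }
  thin <- function(v) {
    if (length(v) <= max_points) seq_along(v)
    else round(seq(1L, length(v), length.out = max_points))
  }
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  ts <- time_axis(x$processed); i <- thin(ts)
  graphics::plot(ts[i], x$processed$samples[i], type = "l", col = "grey30",
                 xlab = "", ylab = "amplitude", main = "processed signal")
  tw <- cw_time_axis(x$tcw); i <- thin(tw)
  graphics::plot(tw[i], x$tcw$values[i], type = "l", col = "steelblue",
                 xlab = "", ylab = "TCW", main = "TCW + segment points")
  graphics::abline(v = x$segmentation$boundaries, col = "grey60", lty = 3)
  tm <- cw_time_axis(x$cmw); i <- thin(tm)
  graphics::plot(tm[i], x$cmw$values[i], type = "l", col = "darkorange",
                 xlab = "time [s]", ylab = "CMW", main = "CMW")
  invisible(x)
}
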