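# Apnea/hypopnea event extraction from the RR series and cycle intervals,
# and the apnea-hypopnea index (AHI).

#' Estimate the stable sleeping respiratory rate
#'
#' Median of the per-minute RR values, ignoring zero-count minutes (which
#' correspond to silence or detector dropout, not breathing). Clinically
#' this is the subject's normal sleeping rate; a user override is
#' accepted everywhere `rr_stable` is consumed.
#'
#' @param rr_series integer vector of per-minute cycle counts (at least
#'   one full minute).
#' @return The stable RR in times/min.
#' @export
estimate_rr_stable <- function(rr_series) {
  rr <- as.numeric(rr_series)
  if (!length(rr)) stop("`rr_series` must contain at least one full minute")
  nz <- rr[rr > 0]
  if (!length(nz)) stop("all minutes have zero detected cycles")
  stats::median(nz)
}

#' Apnea detection threshold on the RR series
#'
#' `T_RR = RR_stable - 10 * RR_stable / 60`: a 10 s pause costs
#' `10 * RR_stable / 60` cycles in a minute, so minutes whose RR falls
#' below this threshold contain at least one clinically long pause. The
#' exact value is returned; rounding is for display only.
#'
#' @param rr_stable stable respiratory rate in times/min (positive).
#' @return The threshold in times/min (`rr_stable * 5 / 6` exactly).
#' @examples
#' rr_threshold(11)  # 9.1667, reported as about 9 times/min
#' @export
rr_threshold <- function(rr_stable) {
  if (!is.numeric(rr_stable) || length(rr_stable) != 1L || rr_stable <= 0) {
    stop("`rr_stable` must be a single positive value")
  }
  rr_stable - 10 * rr_stable / 60
}

#' Minutes whose RR falls below the apnea threshold
#'
#' @param rr_series per-minute RR counts.
#' @param t_rr threshold from [rr_threshold()].
#' @return Integer indices (1-based) of minutes with `RR < t_rr`
#'   (strict inequality).
#' @export
flag_low_rr_minutes <- function(rr_series, t_rr) {
  which(as.numeric(rr_series) < t_rr)
}

#' Breathing pause times from inter-cycle intervals
#'
#' `pause(i) = max(0, dd(i) - 60 / rr_stable)`: each segmented interval
#' contains one breath, so anything beyond one stable cycle length is
#' pause. Short cycles are clamped to zero rather than reported as
#' negative pauses.
#'
#' @param dd numeric vector of inter-boundary intervals in seconds.
#' @param rr_stable stable respiratory rate in times/min (positive).
#' @return Numeric vector of pause durations in seconds.
#' @export
pause_times <- function(dd, rr_stable) {
  if (!is.numeric(rr_stable) || length(rr_stable) != 1L || rr_stable <= 0) {
    stop("`rr_stable` must be a single positive value")
  }
  pmax(0, dd - 60 / rr_stable)
}

#' Classify breathing pauses into apnea and hypopnea events
#'
#' A pause of at least 10 s is an apnea (the clinical definition); a
#' pause of at least `hypo_min` but under 10 s is a hypopnea; shorter
#' pauses are normal breathing variation.
#'
#' @param pauses numeric vector of pause durations in seconds (from
#'   [pause_times()]).
#' @param start_times optional vector of event start times in seconds
#'   (e.g. the boundary that opens each interval); recycled NA if absent.
#' @param hypo_min lower bound for hypopnea in seconds (default 5).
#' @param apnea_min apnea threshold in seconds (default 10, clinical).
#' @return A data frame with columns `type` (`"apnea"`/`"hypopnea"`),
#'   `start_s`, `pause_s`, one row per event.
#' @export
classify_events <- function(pauses, start_times = NULL, hypo_min = 5,
                            apnea_min = 10) {
  if (is.null(start_times)) start_times <- rep(NA_real_, length(pauses))
  stopifnot(length(start_times) == length(pauses))
  sel <- which(pauses >= hypo_min)
  data.frame(
    type = ifelse(pauses[sel] >= apnea_min, "apnea", "hypopnea"),
    start_s = start_times[sel],
    pause_s = pauses[sel]
  )
}

#' Apnea-hypopnea index and severity band
#'
#' `AHI = events / monitored_hours`. By default only apnea events are
#' counted (matching an acoustic-only screen); set
#' `include_hypopnea = TRUE` for the clinical convention. Severity
#' bands: `< 5` normal, `[5, 15)` mild, `[15, 30)` moderate, `>= 30`
#' severe.
#'
#' @param events data frame from [classify_events()], or a single event
#'   count.
#' @param monitored_hours monitoring duration in hours (positive).
#' @param include_hypopnea logical; count hypopnea events too.
#' @return A list with `ahi` (events/hour) and `severity` (character).
#' @export
compute_ahi <- function(events, monitored_hours, include_hypopnea = FALSE) {
  if (!is.numeric(monitored_hours) || length(monitored_hours) != 1L ||
      monitored_hours <= 0) {
    stop("`monitored_hours` must be a single positive value")
  }
  n <- if (is.data.frame(events)) {
    if (include_hypopnea) nrow(events) else sum(events$type == "apnea")
  } else {
    as.numeric(events)
  }
  ahi <- n / monitored_hours
  severity <- if (ahi < 5) "normal" else if (ahi < 15) "mild" else
    if (ahi < 30) "moderate" else "severe"
  list(ahi = ahi, severity = severity)
}

#' Build an apnea report from a segmentation result
#'
#' Ties the pieces together: estimates (or accepts) the stable RR,
#' computes the detection threshold, converts inter-cycle intervals to
#' pause times, classifies events and computes the AHI.
#'
#' @param segmentation a `segmentation_result` from [segment_cycles()].
#' @param rr_stable optional user override for the stable RR (times/min);
#'   if `NULL`, estimated with [estimate_rr_stable()].
#' @param hypo_min hypopnea lower bound in seconds (default 5).
#' @param include_hypopnea logical; include hypopneas in the AHI.
#' @return An object of class `apnea_report`: list with `rr_stable`,
#'   `t_rr`, `flagged_minutes`, `events` (data frame), `ahi`, `severity`,
#'   `monitored_hours`, `include_hypopnea`.
#' @export
apnea_report <- function(segmentation, rr_stable = NULL, hypo_min = 5,
                         include_hypopnea = FALSE) {
  stopifnot(inherits(segmentation, "segmentation_result"))
  if (is.null(rr_stable)) {
    rr_stable <- estimate_rr_stable(segmentation$rr_series)
  }
  t_rr <- rr_threshold(rr_stable)
  pauses <- pause_times(segmentation$dd, rr_stable)
  events <- classify_events(pauses,
                            start_times = utils::head(segmentation$boundaries, -1L),
                            hypo_min = hypo_min)
  hours <- segmentation$duration_s / 3600
  ahi <- compute_ahi(events, hours, include_hypopnea = include_hypopnea)
  structure(list(rr_stable = rr_stable, t_rr = t_rr,
                 flagged_minutes = flag_low_rr_minutes(segmentation$rr_series, t_rr),
                 events = events, ahi = ahi$ahi, severity = ahi$severity,
                 monitored_hours = hours,
                 include_hypopnea = include_hypopnea),
            class = "apnea_report")
}

#' @export
print.apnea_report <- function(x, ...) {
  cat(sprintf("<apnea_report: RR_stable %.1f/min, T_RR %.2f/min, %d apnea + %d hypopnea in %.2f h, AHI %.1f (%s)>\n",
              x$rr_stable, x$t_rr, sum(x$events$type == "apnea"),
              sum(x$events$type == "hypopnea"), x$monitored_hours,
              x$ahi, x$severity))
  if (nrow(x$events)) {
    print(x$events, row.names = FALSE)
  }
  invisible(x)
}

#' Export an apnea report as CSV and JSON
#'
#' @param report an `apnea_report`.
#' @param events_path CSV path for the event table
#'   (`type, start_s, pause_s`).
#' @param summary_path optional JSON path for the summary (`rr_stable`,
#'   `t_rr`, `ahi`, `severity`, `monitored_hours`); requires the
#'   jsonlite package.
#' @return `events_path`, invisibly.
#' @export
write_apnea_csv <- function(report, events_path, summary_path = NULL) {
  stopifnot(inherits(report, "apnea_report"))
  utils::write.csv(report$events, events_path, row.names = FALSE)
  if (!is.null(summary_path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("the jsonlite package is required for JSON summaries")
    }
    jsonlite::write_json(
      list(rr_stable = report$rr_stable, t_rr = report$t_rr,
           ahi = report$ahi, severity = report$severity,
           monitored_hours = report$monitored_hours),
      summary_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(events_path)
}
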