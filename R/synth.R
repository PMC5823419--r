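# Synthetic sleep-breathing sound generator with ground-truth annotations,
# and the boundary-detection success-rate evaluation.

#' Simulator configuration for synthetic sleep breathing
#'
#' Describes a quasi-periodic breathing recording: each cycle is an
#' inspiration burst, an inspiratory pause, an expiration burst and a rest
#' phase; bursts are band-limited white noise under a raised-cosine
#' envelope. Per-cycle peak amplitudes are drawn log-uniformly over the
#' configured max-to-min ratio (weak cycles between strong ones), cycle
#' lengths jitter multiplicatively around the nominal period (real sleep
#' breathing is quasi-periodic with breath-to-breath variability of
#' roughly 5-10%), and zero-mean background noise is added at the
#' configured burst-to-background SNR. Scheduled breathing pauses
#' (apneas/hypopneas) halt the cycle train for exactly `gap_s` seconds at
#' the first cycle boundary at or after `start_s`, then breathing
#' resumes.
#'
#' @param duration_s recording length in seconds.
#' @param cycle_period_s nominal breathing-cycle length in seconds
#'   (default 4; normal sleep breathing is 3-5 s).
#' @param insp_dur_s,exp_dur_s inspiration/expiration burst durations in
#'   seconds, each in `[0.3, 1]`.
#' @param pause_dur_s inspiratory pause between the bursts (seconds).
#' @param amplitude_jitter max-to-min per-cycle peak amplitude ratio
#'   (default 10).
#' @param snr_db burst-to-background power ratio in dB (default 10).
#' @param cycle_jitter_cv coefficient of variation of the per-cycle
#'   period (default 0.07; set 0 for a strictly periodic train).
#' @param apnea_schedule optional data frame with columns `start_s`,
#'   `gap_s` giving requested pause insertions.
#' @param sample_rate output sampling rate in Hz (default 4000, the
#'   pipeline's working rate).
#' @param seed integer RNG seed; fixes the output exactly.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(duration_s = 300, cycle_period_s = 4,
                       insp_dur_s = 0.8, exp_dur_s = 0.8, pause_dur_s = 0.3,
                       amplitude_jitter = 10, snr_db = 10,
                       cycle_jitter_cv = 0.07, apnea_schedule = NULL,
                       sample_rate = 4000, seed = 1L) {
  if (duration_s <= 0) stop("`duration_s` must be positive")
  if (insp_dur_s < 0.3 || insp_dur_s > 1 || exp_dur_s < 0.3 || exp_dur_s > 1) {
    stop("phase durations must lie in [0.3, 1] seconds")
  }
  if (pause_dur_s < 0) stop("`pause_dur_s` must be >= 0")
  if (insp_dur_s + exp_dur_s + pause_dur_s >= cycle_period_s) {
    stop("inspiration + pause + expiration must be shorter than the cycle")
  }
  if (amplitude_jitter < 1) stop("`amplitude_jitter` must be >= 1")
  if (cycle_jitter_cv < 0) stop("`cycle_jitter_cv` must be >= 0")
  if (!is.null(apnea_schedule)) {
    stopifnot(is.data.frame(apnea_schedule),
              all(c("start_s", "gap_s") %in% names(apnea_schedule)))
    if (any(apnea_schedule$start_s < 0) ||
        any(apnea_schedule$start_s + apnea_schedule$gap_s > duration_s)) {
      stop("apnea events must lie within [0, duration_s]")
    }
    apnea_schedule <- apnea_schedule[order(apnea_schedule$start_s), ,
                                     drop = FALSE]
  }
  structure(list(duration_s = duration_s, cycle_period_s = cycle_period_s,
                 insp_dur_s = insp_dur_s, exp_dur_s = exp_dur_s,
                 pause_dur_s = pause_dur_s,
                 amplitude_jitter = amplitude_jitter, snr_db = snr_db,
                 cycle_jitter_cv = cycle_jitter_cv,
                 apnea_schedule = apnea_schedule,
                 sample_rate = sample_rate, seed = as.integer(seed)),
            class = "synth_spec")
}

# Run expr with a private RNG stream seeded by `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic breathing recording with ground truth
#'
#' Deterministic given the spec (including its seed). Ground-truth cycle
#' boundaries are recorded at the midpoint of each cycle's rest phase —
#' the location the detector's TCW minima target — and scheduled
#' breathing pauses are recorded as events with their realized start time
#' and duration (type `"apnea"` for gaps of at least 10 s, else
#' `"hypopnea"`).
#'
#' @param spec a [synth_spec()].
#' @return A list with elements `signal` (an [audio_signal()]) and
#'   `truth` (class `ground_truth`: `cycle_boundaries`, `events`, `spec`).
#' @export
generate_breathing <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  fs <- spec$sample_rate
  n <- round(spec$duration_s * fs)
  active <- spec$insp_dur_s + spec$pause_dur_s + spec$exp_dur_s
  sched <- spec$apnea_schedule
  nev <- if (is.null(sched)) 0L else nrow(sched)

  with_seed(spec$seed, {
    starts <- numeric(0); periods <- numeric(0); amps <- numeric(0)
    ev_start <- numeric(0); ev_gap <- numeric(0)
    t <- 0; e <- 1L
    repeat {
      while (e <= nev && t >= sched$start_s[e] - 1e-9) {
        ev_start <- c(ev_start, t)
        ev_gap <- c(ev_gap, sched$gap_s[e])
        t <- t + sched$gap_s[e]
        e <- e + 1L
      }
      Tk <- spec$cycle_period_s *
        exp(stats::rnorm(1L, 0, spec$cycle_jitter_cv))
      Tk <- max(Tk, active + 0.2)
      if (t + Tk > spec$duration_s + 1e-9) break
      ak <- exp(stats::runif(1L, -log(spec$amplitude_jitter), 0))
      starts <- c(starts, t); periods <- c(periods, Tk); amps <- c(amps, ak)
      t <- t + Tk
    }

    env <- numeric(n)
    add_burst <- function(t0, dur, amp) {
      i0 <- floor(t0 * fs) + 1L
      i1 <- min(n, floor((t0 + dur) * fs))
      if (i1 < i0) return(invisible())
      m <- i1 - i0 + 1L
      # raised-cosine (Hann) envelope
      env[i0:i1] <<- env[i0:i1] +
        amp * 0.5 * (1 - cos(2 * pi * seq_len(m) / (m + 1L)))
    }
    for (k in seq_along(starts)) {
      add_burst(starts[k], spec$insp_dur_s, amps[k])
      add_burst(starts[k] + spec$insp_dur_s + spec$pause_dur_s,
                spec$exp_dur_s, 0.7 * amps[k])
    }

    carrier <- stats::rnorm(n)
    hi <- min(1500, 0.45 * fs)
    bf <- signal::butter(4, c(200, hi) / (fs / 2), type = "pass")
    carrier <- as.numeric(signal::filter(bf, carrier))
    x <- env * carrier

    act <- env > 0
    p_burst <- if (any(act)) mean(x[act]^2) else 1e-6
    sigma <- sqrt(p_burst / 10^(spec$snr_db / 10))
    x <- x + stats::rnorm(n, 0, sigma)

    boundaries <- starts + active + (periods - active) / 2
    events <- data.frame(
      type = if (length(ev_gap)) ifelse(ev_gap >= 10, "apnea", "hypopnea")
             else character(0),
      start_s = ev_start, gap_s = ev_gap
    )
    list(signal = audio_signal(x, fs),
         truth = structure(list(cycle_boundaries = boundaries,
                                events = events, spec = spec),
                           class = "ground_truth"))
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth: %d cycle boundaries, %d events>\n",
              length(x$cycle_boundaries), nrow(x$events)))
  invisible(x)
}

#' Success rate of printed cycle counts
#'
#' The tabulated detection metric: `100 * segmented / manual`, rounded to
#' two decimals — the ratio of the segmented cycle count to the manually
#' counted reference.
#'
#' @param segmented_count number of cycles found by the detector.
#' @param manual_count reference cycle count (positive).
#' @return Percentage rounded to two decimals.
#' @examples
#' success_rate(4921, 5001)  # 98.40
#' @export
success_rate <- function(segmented_count, manual_count) {
  if (any(manual_count <= 0)) stop("`manual_count` must be positive")
  round(100 * segmented_count / manual_count, 2)
}

#' Score detected boundaries against ground truth
#'
#' Greedy one-to-one matching: candidate (detected, true) pairs within
#' `tol_s` are taken in order of increasing time difference, each true
#' boundary used at most once. The success rate is
#' `100 * matched / n_truth` rounded to two decimals; unmatched detected
#' boundaries are counted as false positives.
#'
#' @param detected a `segmentation_result` or numeric vector of detected
#'   boundary times (seconds).
#' @param truth a `ground_truth` or numeric vector of true boundary times.
#' @param tol_s matching tolerance in seconds (default 1.0, positive).
#' @return An object of class `rr_evaluation`: list with `success_rate`
#'   (percent), `matched`, `false_positives`, `n_detected`, `n_truth`,
#'   `tol_s`.
#' @export
evaluate_success_rate <- function(detected, truth, tol_s = 1.0) {
  if (tol_s <= 0) stop("`tol_s` must be positive")
  det <- if (inherits(detected, "segmentation_result")) detected$boundaries
         else as.numeric(detected)
  tru <- if (inherits(truth, "ground_truth")) truth$cycle_boundaries
         else as.numeric(truth)
  if (!length(tru)) stop("ground truth contains no boundaries")
  pairs_i <- integer(0); pairs_j <- integer(0); pairs_d <- numeric(0)
  if (length(det)) {
    lo <- findInterval(det - tol_s - 1e-12, tru) + 1L
    hi <- findInterval(det + tol_s + 1e-12, tru)
    for (i in seq_along(det)) {
      if (lo[i] > hi[i]) next
      j <- lo[i]:hi[i]
      pairs_i <- c(pairs_i, rep(i, length(j)))
      pairs_j <- c(pairs_j, j)
      pairs_d <- c(pairs_d, abs(det[i] - tru[j]))
    }
  }
  used_det <- logical(length(det)); used_tru <- logical(length(tru))
  matched <- 0L
  for (k in order(pairs_d)) {
    i <- pairs_i[k]; j <- pairs_j[k]
    if (!used_det[i] && !used_tru[j]) {
      used_det[i] <- TRUE; used_tru[j] <- TRUE
      matched <- matched + 1L
    }
  }
  structure(list(success_rate = round(100 * matched / length(tru), 2),
                 matched = matched,
                 false_positives = length(det) - matched,
                 n_detected = length(det), n_truth = length(tru),
                 tol_s = tol_s),
            class = "rr_evaluation")
}

#' @export
print.rr_evaluation <- function(x, ...) {
  cat(sprintf("<rr_evaluation: %.2f%% (%d/%d matched within %.2g s, %d false positives)>\n",
              x$success_rate, x$matched, x$n_truth, x$tol_s,
              x$false_positives))
  invisible(x)
}

#' Export ground truth as CSV files
#'
#' @param truth a `ground_truth`.
#' @param boundaries_path CSV path for the cycle-boundary times.
#' @param events_path optional CSV path for the event table.
#' @return `boundaries_path`, invisibly.
#' @export
write_truth_csv <- function(truth, boundaries_path, events_path = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  utils::write.csv(data.frame(index = seq_along(truth$cycle_boundaries),
                              time_s = truth$cycle_boundaries),
                   boundaries_path, row.names = FALSE)
  if (!is.null(events_path)) {
    utils::write.csv(truth$events, events_path, row.names = FALSE)
  }
  invisible(boundaries_path)
}
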