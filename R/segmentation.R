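# Breath-cycle segmentation: CMW maxima and TCW minima -> segment points
# at rest phases, then per-minute cycle counts (the RR series).

# Strict local extrema of a numeric trace with plateau handling: a plateau
# (run of equal values) counts as one extremum at its midpoint time.
local_extrema_times <- function(values, times, minima = FALSE) {
  v <- if (minima) -values else values
  r <- rle(v)
  k <- length(r$values)
  if (k < 3L) return(data.frame(time_s = numeric(0), value = numeric(0)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mid <- 2:(k - 1L)
  is_max <- r$values[mid] > r$values[mid - 1L] & r$values[mid] > r$values[mid + 1L]
  runs <- mid[is_max]
  data.frame(
    time_s = (times[starts[runs]] + times[ends[runs]]) / 2,
    value = if (minima) -r$values[runs] else r$values[runs]
  )
}

# Sparse-table range-maximum structure for vectorized window queries.
rmq_build <- function(v) {
  tab <- list(v)
  j <- 1L
  while (2L^j <= length(v)) {
    prev <- tab[[j]]
    half <- 2L^(j - 1L)
    len <- length(v) - 2L^j + 1L
    tab[[j + 1L]] <- pmax(prev[seq_len(len)], prev[seq_len(len) + half])
    j <- j + 1L
  }
  tab
}

# Vectorized max over index ranges [l, r]; -Inf for empty ranges.
rmq_query <- function(tab, l, r) {
  out <- rep(-Inf, length(l))
  ok <- which(l <= r)
  if (!length(ok)) return(out)
  w <- r[ok] - l[ok] + 1L
  j <- floor(log2(w))
  for (jj in unique(j)) {
    sel <- ok[j == jj]
    half <- 2L^jj
    out[sel] <- pmax(tab[[jj + 1L]][l[sel]], tab[[jj + 1L]][r[sel] - half + 1L])
  }
  out
}

#' Local maxima of a characteristic moment waveform
#'
#' All strict local maxima of the CMW trace (value greater than both
#' neighbours; plateaus yield their midpoint time).
#'
#' @param cmw a `characteristic_waveform` of kind `"cmw_raw"` or
#'   `"cmw_normalized"`.
#' @return A data frame with columns `time_s` and `value`, sorted by time.
#' @export
cmw_maxima <- function(cmw) {
  stopifnot(inherits(cmw, "characteristic_waveform"))
  if (!cmw$kind %in% c("cmw_raw", "cmw_normalized")) {
    stop("`cmw` must be a CMW (kind cmw_raw or cmw_normalized)")
  }
  idx <- cmw$defined[1]:cmw$defined[2]
  if (length(idx) < 3L) stop("CMW too short: fewer than 3 defined samples")
  local_extrema_times(cmw$values[idx], cw_time_axis(cmw)[idx])
}

#' Prominence filter: one dominant maximum per 2*delta window
#'
#' A candidate survives only if no larger candidate (or equal-valued
#' earlier candidate) lies within `delta` seconds of it, i.e. it is the
#' winner of the width-`2 * delta` window centred on it. This keeps
#' exactly one inspiratory energy peak per breathing cycle when `delta`
#' is about half the cycle.
#'
#' @param maxima data frame with columns `time_s`, `value` sorted by time
#'   (as returned by [cmw_maxima()]).
#' @param scales a [scale_params()].
#' @return The surviving rows of `maxima`.
#' @export
prominent_maxima <- function(maxima, scales) {
  stopifnot(is.data.frame(maxima), inherits(scales, "scale_params"))
  k <- nrow(maxima)
  if (k <= 1L) return(maxima)
  t <- maxima$time_s
  v <- maxima$value
  if (is.unsorted(t)) stop("`maxima` must be sorted by time")
  d <- scales$delta
  li <- findInterval(t - d - 1e-12, t) + 1L
  ri <- findInterval(t + d + 1e-12, t)
  tab <- rmq_build(v)
  i <- seq_len(k)
  left_max <- rmq_query(tab, li, i - 1L)   # earlier neighbours in window
  right_max <- rmq_query(tab, i + 1L, ri)  # later neighbours in window
  keep <- left_max < v & right_max <= v    # earlier tie wins
  maxima[keep, , drop = FALSE]
}

#' Prominent local minima of a time characteristic waveform
#'
#' Strict local minima of the TCW (plateau midpoints), filtered with the
#' same one-per-window prominence rule as [prominent_maxima()] applied to
#' the negated trace: the deepest minimum within each `2 * delta` window
#' survives. TCW minima mark the rest phases between breathing cycles.
#'
#' @param tcw a `characteristic_waveform` of kind `"tcw"`.
#' @param scales a [scale_params()].
#' @return A data frame with columns `time_s` and `value` (TCW value at
#'   the minimum), sorted by time.
#' @export
tcw_minima <- function(tcw, scales) {
  stopifnot(inherits(tcw, "characteristic_waveform"))
  if (!identical(tcw$kind, "tcw")) stop("`tcw` must have kind \"tcw\"")
  idx <- tcw$defined[1]:tcw$defined[2]
  if (length(idx) < 3L) return(data.frame(time_s = numeric(0), value = numeric(0)))
  mins <- local_extrema_times(tcw$values[idx], cw_time_axis(tcw)[idx],
                              minima = TRUE)
  if (nrow(mins) <= 1L) return(mins)
  neg <- mins
  neg$value <- -neg$value
  kept <- prominent_maxima(neg, scales)
  kept$value <- -kept$value
  kept
}

#' Segment breathing cycles from TCW and CMW
#'
#' Candidate segment points are the prominent TCW minima (rest phases). A
#' candidate is retained only if at least one prominent CMW maximum lies
#' within `w / 2` seconds of it (the computation window, `w = delta` by
#' default), which rejects minima on flat noise floors. Retained points
#' closer than `min_separation` are merged, keeping the one with the
#' lower TCW value. Inter-cycle intervals `dd(i)` and the per-minute RR
#' series are derived from the final boundaries.
#'
#' @param tcw a `characteristic_waveform` of kind `"tcw"`.
#' @param cmw a `characteristic_waveform` of kind `"cmw_raw"` or
#'   `"cmw_normalized"` on the same time axis.
#' @param scales a [scale_params()].
#' @param w computation-window width in seconds for CMW validation
#'   (default `scales$delta`).
#' @param min_separation minimum spacing between segment points in
#'   seconds (default 1.5, the shortest plausible breathing cycle is
#'   about 2 s).
#' @param validation `"centered"` (default): the validation window is
#'   `[t - w/2, t + w/2]`; `"trailing"`: the window is `[t - w, t]`, so a
#'   boundary must be preceded by a CMW maximum — with raw-CMW burst
#'   peaks this encodes that a cycle boundary closes a cycle and must
#'   follow its expiration, which keeps the breathing restart after an
#'   apnea from being split off as a spurious boundary.
#' @param require_breath logical (default `TRUE`): every segmented
#'   interval must contain a breathing signal. A boundary whose interval
#'   back to the previous kept boundary has a peak TCW below the breath
#'   level (see `breath_frac`) is dropped. This keeps flat silence —
#'   notably apnea gaps — from being chopped into spurious cycles.
#' @param breath_frac an interval counts as containing breath when its
#'   peak TCW exceeds `floor * (burst / floor)^breath_frac`, where
#'   `floor` and `burst` are the 5th and 95th percentiles of the TCW —
#'   i.e. the peak must climb at least this fraction of the recording's
#'   quiescent-to-burst dynamic range on a log scale (default 0.1).
#' @param adjust_boundaries logical (default `TRUE`): re-anchor each
#'   segment point within its quiet (sub-threshold TCW) run. A rest
#'   phase between two cycles yields a run of roughly the rest duration
#'   and the point moves to its midpoint; a run much longer than typical
#'   (a breathing pause) keeps the point anchored at half a typical rest
#'   after the run's start, i.e. where the rest of the cycle it closes
#'   would have ended. This removes the placement wobble of minima on
#'   flat silence, which otherwise biases apnea pause estimates.
#' @return An object of class `segmentation_result`: list with
#'   `boundaries` (segment-point times, seconds), `dd` (successive
#'   differences), `rr_series` (cycle counts per full tumbling minute),
#'   `rr_partial` (+ `rr_partial_s`, trailing partial minute), `scales`,
#'   `duration_s`. If no boundaries are found an empty result is returned
#'   with a warning.
#' @export
segment_cycles <- function(tcw, cmw, scales, w = NULL, min_separation = 1.5,
                           validation = c("centered", "trailing"),
                           require_breath = TRUE, breath_frac = 0.1,
                           adjust_boundaries = TRUE) {
  stopifnot(inherits(tcw, "characteristic_waveform"),
            inherits(cmw, "characteristic_waveform"),
            inherits(scales, "scale_params"))
  validation <- match.arg(validation)
  if (is.null(w)) w <- scales$delta
  dur <- length(tcw$values) / tcw$sample_rate
  empty <- function() {
    warning("no breath-cycle boundaries found")
    rr <- rr_per_minute(numeric(0), dur)
    structure(list(boundaries = numeric(0), dd = numeric(0),
                   rr_series = rr, rr_partial = attr(rr, "partial"),
                   rr_partial_s = attr(rr, "partial_s"),
                   scales = scales, duration_s = dur),
              class = "segmentation_result")
  }
  cand <- tcw_minima(tcw, scales)
  if (nrow(cand) == 0L) return(empty())
  peaks <- prominent_maxima(cmw_maxima(cmw), scales)
  if (nrow(peaks) == 0L) return(empty())
  # retain candidates with a prominent CMW maximum in the validation window
  pt <- peaks$time_s
  near <- findInterval(cand$time_s, pt)
  d_lo <- ifelse(near >= 1L, cand$time_s - pt[pmax(near, 1L)], Inf)
  d_hi <- ifelse(near < length(pt), pt[pmin(near + 1L, length(pt))] - cand$time_s, Inf)
  ok <- if (validation == "centered") pmin(d_lo, d_hi) <= w / 2 + 1e-12
        else d_lo <= w + 1e-12
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty())
  # merge points closer than min_separation, keeping the lower-TCW one
  bt <- numeric(0)
  bv <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (length(bt) && cand$time_s[i] - bt[length(bt)] < min_separation) {
      if (cand$value[i] < bv[length(bv)]) {
        bt[length(bt)] <- cand$time_s[i]
        bv[length(bv)] <- cand$value[i]
      }
    } else {
      bt <- c(bt, cand$time_s[i])
      bv <- c(bv, cand$value[i])
    }
  }
  # breath-level threshold on the TCW: quiescent floor raised by a
  # fraction of the floor-to-burst dynamic range (log scale)
  v <- tcw$values
  fs <- tcw$sample_rate
  t0 <- tcw$start_time
  d1 <- tcw$defined[1]; d2 <- tcw$defined[2]
  dv <- v[d1:d2]
  flo <- stats::quantile(dv, 0.05, names = FALSE)
  hi <- stats::quantile(dv, 0.95, names = FALSE)
  thr <- if (flo <= 0 || hi <= flo) flo else flo * (hi / flo)^breath_frac

  # every segmented part must contain a breathing signal: drop boundaries
  # that close a breathless interval (flat silence, e.g. an apnea gap)
  if (require_breath && length(bt) > 1L) {
    has_breath <- function(a, b) {
      i1 <- max(d1, floor((a - t0) * fs) + 1L)
      i2 <- min(d2, ceiling((b - t0) * fs) + 1L)
      i2 > i1 && max(v[i1:i2]) > thr
    }
    keep <- logical(length(bt))
    keep[1L] <- TRUE
    last <- bt[1L]
    for (i in 2:length(bt)) {
      if (has_breath(last, bt[i])) {
        keep[i] <- TRUE
        last <- bt[i]
      }
    }
    bt <- bt[keep]
  }

  # re-anchor each segment point within its quiet run (see Arguments)
  if (adjust_boundaries && length(bt) && hi > flo) {
    quiet <- rle(dv < thr)
    q_end <- cumsum(quiet$lengths)
    q_start <- q_end - quiet$lengths + 1L
    qs <- which(quiet$values)
    if (length(qs)) {
      run_a <- t0 + (d1 + q_start[qs] - 2L) / fs   # run start times
      run_b <- t0 + (d1 + q_end[qs] - 1L) / fs     # run end times
      ri <- findInterval(bt, run_a)
      inside <- ri >= 1L & bt <= run_b[pmax(ri, 1L)] + 1e-12
      # only move a point that is alone in its run: a run swallowing
      # several boundaries (weak cycles under the threshold) keeps them
      alone <- inside & !(duplicated(ri) | duplicated(ri, fromLast = TRUE))
      if (any(alone)) {
        len_all <- (run_b - run_a)[ri[inside]]
        typical <- stats::median(len_all)
        len <- (run_b - run_a)[ri[alone]]
        # rest-like runs move to their midpoint; pause-like runs (well
        # beyond a rest) anchor at half a typical rest after run start;
        # ambiguous lengths (e.g. a weak cycle swallowed by the
        # threshold) are left where the minima put them
        restlike <- len <= 1.5 * typical
        pauselike <- len >= typical + 4
        move <- alone
        move[alone] <- restlike | pauselike
        mlen <- len[restlike | pauselike]
        bt[move] <- run_a[ri[move]] + pmin(mlen, typical) / 2
      }
      bt <- sort(bt)
    }
  }
  rr <- rr_per_minute(bt, dur)
  structure(list(boundaries = bt, dd = diff(bt), rr_series = rr,
                 rr_partial = attr(rr, "partial"),
                 rr_partial_s = attr(rr, "partial_s"),
                 scales = scales, duration_s = dur),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result: %d boundaries over %.1f s; RR per minute: %s%s>\n",
              length(x$boundaries), x$duration_s,
              paste(as.vector(x$rr_series), collapse = " "),
              if (x$rr_partial_s > 0)
                sprintf(" (+%d in %.0f s partial)", x$rr_partial, x$rr_partial_s)
              else ""))
  invisible(x)
}

#' Per-minute respiratory-rate series
#'
#' Counts segment points in tumbling 60 s windows `[60k, 60(k+1))`
#' (half-open: a boundary exactly at a window edge belongs to the later
#' window). The trailing partial minute is reported separately via
#' attributes and never scaled up.
#'
#' @param result a `segmentation_result` or a numeric vector of
#'   segment-point times in seconds.
#' @param total_duration recording duration in seconds.
#' @return Integer vector of counts for each full minute, with attributes
#'   `partial` (count in the trailing partial minute) and `partial_s`
#'   (its length in seconds).
#' @export
rr_per_minute <- function(result, total_duration) {
  b <- if (inherits(result, "segmentation_result")) result$boundaries else result
  if (length(b) && (min(b) < 0 || max(b) > total_duration)) {
    stop("boundaries must lie within [0, total_duration]")
  }
  full <- floor(total_duration / 60)
  k <- floor(b / 60)
  counts <- if (full > 0) tabulate(k[k < full] + 1L, nbins = full) else integer(0)
  structure(as.integer(counts),
            partial = sum(k >= full),
            partial_s = total_duration - 60 * full)
}

#' Export segment points and RR series as CSV
#'
#' @param result a `segmentation_result`.
#' @param boundaries_path CSV path for columns `index, time_s, dd_s`
#'   (`dd_s` is the interval ending at that boundary; NA for the first).
#' @param rr_path optional CSV path for columns `minute_index, rr`.
#' @return `boundaries_path`, invisibly.
#' @export
write_segmentation_csv <- function(result, boundaries_path, rr_path = NULL) {
  stopifnot(inherits(result, "segmentation_result"))
  df <- data.frame(index = seq_along(result$boundaries),
                   time_s = result$boundaries,
                   dd_s = c(NA, result$dd))
  utils::write.csv(df, boundaries_path, row.names = FALSE)
  if (!is.null(rr_path)) {
    rr <- data.frame(minute_index = seq_along(result$rr_series),
                     rr = as.vector(result$rr_series))
    utils::write.csv(rr, rr_path, row.names = FALSE)
  }
  invisible(boundaries_path)
}
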