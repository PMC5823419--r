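#' Time-scale parameters for the characteristic waveforms
#'
#' @param delta TCW half-window in seconds; about half a breathing cycle,
#'   recommended range `[1.5, 3]`.
#' @param moment_l CMW half-window in seconds (default 0.1, about a tenth
#'   of an inspiration/expiration phase); must satisfy
#'   `0 < moment_l < delta`.
#' @return An object of class `scale_params`.
#' @export
scale_params <- function(delta = 2.5, moment_l = 0.1) {
  if (!(moment_l > 0 && moment_l < delta)) {
    stop("scales must satisfy 0 < moment_l < delta")
  }
  structure(list(delta = delta, moment_l = moment_l), class = "scale_params")
}

#' Suggest TCW/CMW scales from an estimated breathing-cycle length
#'
#' The TCW half-window is set to half the cycle, clipped to the
#' recommended `[1.5, 3]` s range; the CMW half-window is fixed at 0.1 s.
#'
#' @param estimated_cycle_s estimated breathing-cycle length in seconds,
#'   in `[2, 10]`.
#' @return A [scale_params()].
#' @examples
#' suggest_scales(4)  # delta = 2.0
#' suggest_scales(5)  # delta = 2.5
#' @export
suggest_scales <- function(estimated_cycle_s) {
  if (!is.numeric(estimated_cycle_s) || length(estimated_cycle_s) != 1L ||
      estimated_cycle_s < 2 || estimated_cycle_s > 10) {
    stop("`estimated_cycle_s` must be a single value in [2, 10] seconds")
  }
  scale_params(delta = min(3, max(1.5, estimated_cycle_s / 2)), moment_l = 0.1)
}

new_characteristic_waveform <- function(values, sample_rate, start_time,
                                        kind, scales, defined) {
  structure(list(values = values, sample_rate = sample_rate,
                 start_time = start_time, kind = kind, scales = scales,
                 defined = defined),
            class = "characteristic_waveform")
}

#' @export
print.characteristic_waveform <- function(x, ...) {
  cat(sprintf("<characteristic_waveform [%s]: %d samples @ %g Hz, defined %d..%d, delta=%g l=%g>\n",
              x$kind, length(x$values), x$sample_rate,
              x$defined[1], x$defined[2], x$scales$delta, x$scales$moment_l))
  invisible(x)
}

#' Time axis of a characteristic waveform
#' @param cw a `characteristic_waveform`.
#' @return Numeric vector of sample times in seconds (full axis; entries
#'   outside the defined range hold `NA` values in `cw$values`).
#' @export
cw_time_axis <- function(cw) {
  stopifnot(inherits(cw, "characteristic_waveform"))
  cw$start_time + (seq_along(cw$values) - 1) / cw$sample_rate
}

#' Time characteristic waveform (sliding-window variance)
#'
#' Computes `c(t, delta) = S2(t) - S1(t)^2 / w` where `S2` and `S1` are
#' windowed Riemann integrals (sample sums divided by the sample rate) of
#' `y^2` and `y` over `[t - delta, t + delta]`, and `w` is the effective
#' window length. The window is realized as the inclusive index range
#' `[i - r, i + r]` with `r = round(delta * fs)` and `w = (2r + 1) / fs`,
#' so a constant signal yields exactly zero. Two prefix-sum passes give
#' O(n) cost independent of `delta`. The first and last `r` samples have
#' no value (`NA`); negative round-off is clamped to zero.
#'
#' @param signal an [audio_signal()] with duration greater than
#'   `2 * delta`.
#' @param scales a [scale_params()].
#' @return A `characteristic_waveform` of kind `"tcw"` aligned to the
#'   signal's time axis. Units: amplitude^2 * seconds.
#' @export
tcw <- function(signal, scales) {
  stopifnot(inherits(signal, "audio_signal"), inherits(scales, "scale_params"))
  y <- signal$samples
  fs <- signal$sample_rate
  n <- length(y)
  r <- as.integer(round(scales$delta * fs))
  if (n <= 2L * r) {
    stop("signal too short: duration must exceed 2 * delta (",
         2 * scales$delta, " s)")
  }
  p1 <- c(0, cumsum(y))
  p2 <- c(0, cumsum(y * y))
  i <- (r + 1L):(n - r)
  s1 <- (p1[i + r + 1L] - p1[i - r]) / fs
  s2 <- (p2[i + r + 1L] - p2[i - r]) / fs
  w <- (2L * r + 1L) / fs
  v <- rep(NA_real_, n)
  v[i] <- pmax(0, s2 - s1 * s1 / w)
  new_characteristic_waveform(v, fs, signal$start_time, "tcw", scales,
                              defined = c(r + 1L, n - r))
}

# Exact moments of the piecewise-linear interpolant of c over [x1, x2]
# (one cell or sub-cell; cx1, cx2 are the interpolated values at the ends):
#   m0 = integral of c, m1 = integral of x*c, m2 = integral of x^2*c.
cell_m0 <- function(x1, x2, cx1, cx2) (x2 - x1) * (cx1 + cx2) / 2
cell_m1 <- function(x1, x2, cx1, cx2) {
  (x2 - x1) * (cx1 * (2 * x1 + x2) + cx2 * (x1 + 2 * x2)) / 6
}
cell_m2 <- function(x1, x2, cx1, cx2) {
  (x2 - x1) * (cx1 * (3 * x1^2 + 2 * x1 * x2 + x2^2) +
               cx2 * (x1^2 + 2 * x1 * x2 + 3 * x2^2)) / 12
}

#' Characteristic moment waveform (local second moment of the TCW)
#'
#' For each time `t`, integrates `(tau - t)^2 * c(tau, delta)` over the
#' window `[t - l, t + l]` (raw form), optionally normalized by the local
#' TCW mass `integral of c(tau, delta)` over the same window. The TCW is
#' treated as piecewise linear between samples and both integrals are
#' evaluated exactly on that interpolant (including fractional end cells),
#' so a constant TCW gives the closed-form normalized value `l^2 / 3`
#' exactly. Implemented with prefix sums of per-cell moments of `c`,
#' `tau * c` and `tau^2 * c` — O(n) regardless of `l` — with the time
#' origin re-centred per processing block to avoid cancellation on long
#' recordings.
#'
#' Where the local TCW mass is below `eps` (a dead-silent window), the
#' normalized value is defined as `moment_l^2 / 3`, its constant-input
#' limit.
#'
#' @param signal_tcw a `characteristic_waveform` of kind `"tcw"` from
#'   [tcw()], defined over a span greater than `2 * moment_l`.
#' @param scales a [scale_params()].
#' @param normalized logical; if `TRUE` (default) return the normalized
#'   form (units seconds^2, values in `[0, moment_l^2]`), otherwise the
#'   raw moment integral.
#' @param eps threshold on the local TCW mass below which the normalized
#'   value falls back to the constant-input limit (default `1e-12`).
#' @return A `characteristic_waveform` of kind `"cmw_normalized"` or
#'   `"cmw_raw"` on the same time axis as the input.
#' @export
cmw <- function(signal_tcw, scales, normalized = TRUE, eps = 1e-12) {
  stopifnot(inherits(signal_tcw, "characteristic_waveform"),
            inherits(scales, "scale_params"))
  if (!identical(signal_tcw$kind, "tcw")) {
    stop("`signal_tcw` must be a TCW (kind == \"tcw\")")
  }
  cvals <- signal_tcw$values
  fs <- signal_tcw$sample_rate
  l <- scales$moment_l
  i0 <- signal_tcw$defined[1]
  i1 <- signal_tcw$defined[2]
  if ((i1 - i0) / fs <= 2 * l) {
    stop("TCW defined span must exceed 2 * moment_l")
  }
  h <- 1 / fs
  K <- l * fs
  kf <- floor(K + 1e-9)
  frac <- K - kf
  aligned <- frac < 1e-9
  # margin of samples needed on each side of a centre
  marg <- if (aligned) kf else kf + 1L
  ia <- i0 + marg
  ib <- i1 - marg
  if (ia > ib) stop("TCW defined span too short for moment_l")

  out <- rep(NA_real_, length(cvals))
  lim <- l^2 / 3
  # short blocks keep the prefix-sum totals commensurate with the tiny
  # windowed moments being extracted (the re-centred |tau| never grows
  # past ~1 s), which holds the cancellation error well below 1e-9
  block <- max(64L, as.integer(round(2 * fs)))
  ca <- ia
  while (ca <= ib) {
    cb <- min(ib, ca + block - 1L)
    lo <- ca - marg          # sample range needed for this block
    hi <- cb + marg
    mid <- (lo + hi) %/% 2L  # local time origin (sample index)
    u <- (lo:hi - mid) * h   # local sample times
    cc <- cvals[lo:hi]
    nn <- length(cc)
    # prefix sums of full-cell moments (cell j spans u[j]..u[j+1])
    j1 <- 1:(nn - 1L)
    PM0 <- c(0, cumsum(cell_m0(u[j1], u[j1 + 1L], cc[j1], cc[j1 + 1L])))
    PM1 <- c(0, cumsum(cell_m1(u[j1], u[j1 + 1L], cc[j1], cc[j1 + 1L])))
    PM2 <- c(0, cumsum(cell_m2(u[j1], u[j1 + 1L], cc[j1], cc[j1 + 1L])))
    ci <- ca:cb              # absolute centre indices
    li <- ci - lo + 1L       # local centre indices into u/cc
    ui <- u[li]
    if (aligned) {
      ka <- li - kf          # first full cell (left-sample index)
      kb <- li + kf - 1L     # last full cell
      S0 <- PM0[kb + 1L] - PM0[ka]
      S1 <- PM1[kb + 1L] - PM1[ka]
      S2 <- PM2[kb + 1L] - PM2[ka]
      num <- S2 - 2 * ui * S1 + ui * ui * S0
      den <- S0
    } else {
      ka <- li - kf
      kb <- li + kf - 1L
      S0 <- PM0[kb + 1L] - PM0[ka]
      S1 <- PM1[kb + 1L] - PM1[ka]
      S2 <- PM2[kb + 1L] - PM2[ka]
      # partial end cells; positions relative to the centre are the same
      # for every centre: left spans [-l, -kf*h], right [kf*h, l]
      cLo <- cc[li - kf - 1L]; cLi <- cc[li - kf]
      cRi <- cc[li + kf];      cRo <- cc[li + kf + 1L]
      c_at_a <- cLo + (cLi - cLo) * (1 - frac)  # value at t - l
      c_at_b <- cRi + (cRo - cRi) * frac        # value at t + l
      x1L <- -l; x2L <- -kf * h
      x1R <- kf * h; x2R <- l
      num <- (S2 - 2 * ui * S1 + ui * ui * S0) +
        cell_m2(x1L, x2L, c_at_a, cLi) + cell_m2(x1R, x2R, cRi, c_at_b)
      den <- S0 + cell_m0(x1L, x2L, c_at_a, cLi) +
        cell_m0(x1R, x2R, cRi, c_at_b)
    }
    if (normalized) {
      val <- ifelse(den < eps, lim, num / den)
      # clamp round-off excursions outside the attainable range
      out[ci] <- pmin(pmax(val, 0), l^2)
    } else {
      out[ci] <- pmax(num, 0)
    }
    ca <- cb + 1L
  }
  new_characteristic_waveform(
    out, fs, signal_tcw$start_time,
    if (normalized) "cmw_normalized" else "cmw_raw",
    scales, defined = c(ia, ib)
  )
}

#' Export a characteristic waveform as a two-column CSV
#'
#' Writes `time_s, value` rows for the defined region of the waveform,
#' for plotting or debugging.
#'
#' @param cw a `characteristic_waveform`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(cw, path) {
  stopifnot(inherits(cw, "characteristic_waveform"))
  idx <- cw$defined[1]:cw$defined[2]
  df <- data.frame(time_s = cw_time_axis(cw)[idx], value = cw$values[idx])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
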