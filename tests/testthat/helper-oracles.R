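`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force oracles for the windowed-variance (TCW) and
# local-second-moment (CMW) waveforms. These evaluate the defining
# integrals directly, per centre point, with no prefix sums and no
# origin re-centring — deliberately a different computational path from
# the package implementation.

# Windowed variance at every interior sample: Riemann sums over the
# inclusive index window [i - r, i + r], effective window (2r + 1) / fs.
brute_tcw <- function(y, fs, delta) {
  n <- length(y)
  r <- as.integer(round(delta * fs))
  w <- (2 * r + 1) / fs
  out <- rep(NA_real_, n)
  for (i in (r + 1):(n - r)) {
    win <- y[(i - r):(i + r)]
    s1 <- sum(win) / fs
    s2 <- sum(win^2) / fs
    out[i] <- max(0, s2 - s1 * s1 / w)
  }
  out
}

# Exact integrals of the piecewise-linear interpolant of c over
# [t - l, t + l]: returns second moment about t (num), mass (den).
# Absolute-time evaluation, cell by cell.
brute_cmw_point <- function(cvals, fs, i, l) {
  h <- 1 / fs
  tt <- (i - 1) / fs
  a <- tt - l
  b <- tt + l
  interp <- function(x) {
    j <- floor(x * fs) + 1
    x0 <- (j - 1) / fs
    cvals[j] + (cvals[j + 1] - cvals[j]) * (x - x0) / h
  }
  seg <- function(x1, x2) {
    c1 <- interp(x1); c2 <- interp(x2 - 1e-15)
    m0 <- (x2 - x1) * (c1 + c2) / 2
    m2 <- (x2 - x1) * (c1 * (3 * x1^2 + 2 * x1 * x2 + x2^2) +
                       c2 * (x1^2 + 2 * x1 * x2 + 3 * x2^2)) / 12
    # second moment about t = integral of (x - t)^2 c: shift via m1
    m1 <- (x2 - x1) * (c1 * (2 * x1 + x2) + c2 * (x1 + 2 * x2)) / 6
    c(m0 = m0, mom = m2 - 2 * tt * m1 + tt^2 * m0)
  }
  knots <- ((ceiling(a * fs - 1e-9)):(floor(b * fs + 1e-9))) / fs
  pts <- sort(unique(c(a, knots[knots > a & knots < b], b)))
  tot <- c(m0 = 0, mom = 0)
  for (k in seq_len(length(pts) - 1)) tot <- tot + seg(pts[k], pts[k + 1])
  tot
}

# Synthetic bursty "breathing-like" test vector without the simulator
# (cheap fixture for segmentation edge cases).
burst_train <- function(duration, period, burst, fs, amps = NULL,
                        noise = 0.01, seed = 42) {
  set.seed(seed)
  n <- round(duration * fs)
  x <- rnorm(n, 0, noise)
  starts <- seq(0, duration - period, by = period)
  if (is.null(amps)) amps <- rep(1, length(starts))
  for (k in seq_along(starts)) {
    i0 <- round(starts[k] * fs) + 1
    i1 <- min(n, i0 + round(burst * fs))
    m <- i1 - i0 + 1
    x[i0:i1] <- x[i0:i1] +
      amps[k] * sin(pi * seq_len(m) / m) * rnorm(m)
  }
  audio_signal(x, fs)
}
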