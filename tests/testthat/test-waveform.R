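test_that("TCW of a constant signal is exactly zero", {
  sig <- audio_signal(rep(0.7, 2000), 200)
  tc <- tcw(sig, scale_params(1, 0.1))
  idx <- tc$defined[1]:tc$defined[2]
  expect_lt(max(tc$values[idx]), 1e-12)   # clamped round-off only
  expect_true(all(tc$values[idx] >= 0))
  expect_true(all(is.na(tc$values[-idx])))
})

test_that("TCW matches the closed-form variance of a linear ramp", {
  # y(tau) = tau on [t - 1, t + 1]: integral tau^2 = 2/3, mean term 0
  fs <- 4000
  tt <- seq(-2, 2, by = 1 / fs)
  sig <- audio_signal(tt, fs)
  tc <- tcw(sig, scale_params(1, 0.1))
  centre <- which.min(abs(tt))
  expect_equal(tc$values[centre], 2 / 3, tolerance = 2e-3)
})

test_that("prefix-sum TCW and CMW match brute-force evaluation", {
  set.seed(123)
  n_signals <- 30
  worst_tcw <- 0
  worst_cmw <- 0
  for (k in seq_len(n_signals)) {
    fs <- sample(c(200, 500, 1000), 1)
    n <- sample(400:3000, 1)
    delta <- runif(1, 0.05, 0.4)
    r <- round(delta * fs)
    if (r < 2) delta <- 3 / fs
    # mix aligned (integer l * fs) and fractional moment windows
    l <- if (k %% 2 == 0) max(2, round(delta * fs / 3)) / fs
         else delta * runif(1, 0.2, 0.6)
    if (l >= delta) l <- delta * 0.5
    n <- max(n, ceiling(2 * (delta + l) * fs) + 50)
    y <- rnorm(n)
    sig <- audio_signal(y, fs)
    sc <- scale_params(delta, l)
    tc <- tcw(sig, sc)
    ref <- brute_tcw(y, fs, delta)
    idx <- tc$defined[1]:tc$defined[2]
    scale <- pmax(abs(ref[idx]), 1e-6)
    worst_tcw <- max(worst_tcw, max(abs(tc$values[idx] - ref[idx]) / scale))

    cm_n <- cmw(tc, sc, normalized = TRUE)
    cm_r <- cmw(tc, sc, normalized = FALSE)
    centres <- sample(cm_n$defined[1]:cm_n$defined[2], 25)
    for (i in centres) {
      ref2 <- brute_cmw_point(tc$values, fs, i, l)
      worst_cmw <- max(worst_cmw,
                       abs(cm_r$values[i] - ref2[["mom"]]) /
                         max(abs(ref2[["mom"]]), 1e-12),
                       abs(cm_n$values[i] - ref2[["mom"]] / ref2[["m0"]]) /
                         max(abs(ref2[["mom"]] / ref2[["m0"]]), 1e-12))
    }
  }
  expect_lt(worst_tcw, 1e-9)
  expect_lt(worst_cmw, 1e-9)
})

test_that("normalized CMW of constant and linear TCW is moment_l^2 / 3", {
  fs <- 1000
  sc <- scale_params(0.5, 0.1)
  mk_tcw <- function(v) {
    cmwbreath:::new_characteristic_waveform(v, fs, 0, "tcw", sc,
                                            c(1L, length(v)))
  }
  const <- mk_tcw(rep(2.5, 2000))
  cm <- cmw(const, sc)
  idx <- cm$defined[1]:cm$defined[2]
  expect_equal(cm$values[idx], rep(0.1^2 / 3, length(idx)), tolerance = 1e-12)

  # linear trend invariance: c(tau) = alpha * tau, positive on the span
  lin <- mk_tcw(seq(1, 5, length.out = 3000))
  cm <- cmw(lin, sc)
  idx <- cm$defined[1]:cm$defined[2]
  expect_equal(cm$values[idx], rep(0.1^2 / 3, length(idx)), tolerance = 1e-10)

  # dead-silent window falls back to the constant-input limit
  dead <- mk_tcw(numeric(1500))
  cm <- cmw(dead, sc)
  idx <- cm$defined[1]:cm$defined[2]
  expect_equal(cm$values[idx], rep(0.1^2 / 3, length(idx)))
})

test_that("TCW is nonnegative and normalized CMW stays in [0, l^2]", {
  set.seed(9)
  for (k in 1:5) {
    sig <- audio_signal(rnorm(3000), 500)
    sc <- scale_params(0.3, 0.08)
    tc <- tcw(sig, sc)
    idx <- tc$defined[1]:tc$defined[2]
    expect_true(all(tc$values[idx] >= 0))
    cm <- cmw(tc, sc)
    idx <- cm$defined[1]:cm$defined[2]
    expect_true(all(cm$values[idx] >= 0 & cm$values[idx] <= 0.08^2))
  }
})

test_that("TCW is shift-equivariant away from boundaries", {
  set.seed(21)
  fs <- 500
  y <- rnorm(2500)
  shift <- 100L
  sc <- scale_params(0.25, 0.05)
  a <- tcw(audio_signal(y, fs), sc)$values
  b <- tcw(audio_signal(y[-(1:shift)], fs), sc)$values
  r <- round(0.25 * fs)
  ia <- (r + 1 + shift):(2500 - r - shift)
  expect_equal(a[ia], b[ia - shift], tolerance = 1e-10)
})

test_that("signals shorter than the window are rejected", {
  sig <- audio_signal(rnorm(100), 100)
  expect_error(tcw(sig, scale_params(1, 0.1)), "too short")
  tc <- tcw(audio_signal(rnorm(1000), 100), scale_params(1, 0.1))
  expect_error(cmw(tc, scale_params(5, 4)), "span")
  expect_error(cmw(audio_signal(1:10, 10), scale_params(1, 0.1)), "tcw")
})

test_that("suggest_scales follows the half-cycle rule with clipping", {
  expect_equal(suggest_scales(4)$delta, 2.0)
  expect_equal(suggest_scales(4)$moment_l, 0.1)
  expect_equal(suggest_scales(5)$delta, 2.5)
  expect_equal(suggest_scales(10)$delta, 3.0)
  expect_equal(suggest_scales(2)$delta, 1.5)
  expect_error(suggest_scales(1.5), "estimated_cycle_s")
  expect_error(suggest_scales(12), "estimated_cycle_s")
})

test_that("scale_params enforces 0 < moment_l < delta", {
  expect_error(scale_params(1, 1.5), "moment_l")
  expect_error(scale_params(1, 0), "moment_l")
})

test_that("waveform CSV export writes time/value pairs", {
  sig <- audio_signal(rnorm(500), 100)
  tc <- tcw(sig, scale_params(0.5, 0.1))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(tc, tmp)
  df <- read.csv(tmp)
  expect_named(df, c("time_s", "value"))
  expect_equal(nrow(df), diff(tc$defined) + 1)
})
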