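make_cw <- function(values, fs, kind, sc) {
  cmwbreath:::new_characteristic_waveform(values, fs, 0, kind, sc,
                                          c(1L, length(values)))
}

test_that("cmw_maxima finds strict maxima, plateaus and rejects monotone traces", {
  sc <- scale_params(2, 0.1)
  tri <- make_cw(c(0, 1, 2, 3, 2, 1, 0), 1, "cmw_normalized", sc)
  mx <- cmw_maxima(tri)
  expect_equal(nrow(mx), 1)
  expect_equal(mx$time_s, 3)  # apex at sample 4, time 3 s at 1 Hz

  mono <- make_cw(1:10, 1, "cmw_normalized", sc)
  expect_equal(nrow(cmw_maxima(mono)), 0)

  plateau <- make_cw(c(0, 2, 2, 2, 0), 1, "cmw_raw", sc)
  expect_equal(cmw_maxima(plateau)$time_s, 2)  # midpoint of the run

  set.seed(4)
  v <- runif(500)
  tr <- make_cw(v, 10, "cmw_normalized", sc)
  got <- cmw_maxima(tr)$time_s
  # exhaustive neighbour scan as oracle
  ora <- (which(v[2:499] > v[1:498] & v[2:499] > v[3:500]) + 1 - 1) / 10
  expect_equal(got, ora)

  short <- make_cw(c(1, 2), 1, "cmw_raw", sc)
  expect_error(cmw_maxima(short), "too short")
  expect_error(cmw_maxima(make_cw(1:5, 1, "tcw", sc)), "CMW")
})

test_that("prominence filter keeps one dominant extremum per window", {
  sc <- scale_params(2, 0.1)
  two <- data.frame(time_s = c(10, 10.3), value = c(1.0, 0.4))
  expect_equal(prominent_maxima(two, sc)$time_s, 10)

  far <- data.frame(time_s = c(10, 15), value = c(1.0, 0.4))
  expect_equal(prominent_maxima(far, sc)$time_s, c(10, 15))

  tie <- data.frame(time_s = c(10, 10.3), value = c(0.7, 0.7))
  expect_equal(prominent_maxima(tie, sc)$time_s, 10)
})

test_that("tcw_minima mirrors the prominence rule on the negated trace", {
  sc <- scale_params(2, 0.1)
  vee <- make_cw(c(3, 2, 1, 0.5, 1, 2, 3), 1, "tcw", sc)
  mn <- tcw_minima(vee, sc)
  expect_equal(nrow(mn), 1)
  expect_equal(mn$time_s, 3)
  expect_equal(mn$value, 0.5)

  expect_equal(nrow(tcw_minima(make_cw(rep(2, 50), 1, "tcw", sc), sc)), 0)

  # periodic trace of period T with delta = T/2: about duration / T minima
  fs <- 50; T <- 4
  tt <- (0:(fs * 60 - 1)) / fs
  per <- make_cw(2 + cos(2 * pi * tt / T), fs, "tcw", scale_params(T / 2, 0.1))
  n_min <- nrow(tcw_minima(per, scale_params(T / 2, 0.1)))
  expect_true(abs(n_min - 60 / T) <= 1)
})

test_that("a TCW minimum with no CMW maximum in the window is rejected", {
  fs <- 10
  sc <- scale_params(1, 0.1)
  # dip at t = 5 between two shoulders, but a featureless (constant) CMW
  tt <- (0:120) / fs
  tcv <- 1 + (tt - 6)^2 / 10
  tc <- make_cw(tcv, fs, "tcw", sc)
  cm <- make_cw(rep(0.003, length(tcv)), fs, "cmw_normalized", sc)
  expect_warning(res <- segment_cycles(tc, cm, sc, require_breath = FALSE,
                                       adjust_boundaries = FALSE),
                 "no breath-cycle boundaries")
  expect_length(res$boundaries, 0)
  expect_length(res$dd, 0)
})

test_that("segmentation recovers the cycles of a clean synthetic recording", {
  sim <- generate_breathing(synth_spec(duration_s = 64, cycle_period_s = 4,
                                       amplitude_jitter = 2, snr_db = 20,
                                       cycle_jitter_cv = 0, seed = 2))
  expect_length(sim$truth$cycle_boundaries, 16)
  det <- suppressWarnings(cmw_detect(sim$signal, pipeline_config()))
  expect_length(det$segmentation$boundaries, 16)
  ev <- evaluate_success_rate(det$segmentation, sim$truth)
  expect_equal(ev$success_rate, 100)

  # apnea case: nine cycles, one interval much longer than the rest
  sim9 <- generate_breathing(synth_spec(duration_s = 60, cycle_period_s = 5,
                                        amplitude_jitter = 2, snr_db = 20,
                                        cycle_jitter_cv = 0,
                                        apnea_schedule = data.frame(
                                          start_s = 25, gap_s = 14),
                                        seed = 2))
  expect_length(sim9$truth$cycle_boundaries, 9)
  det9 <- suppressWarnings(cmw_detect(sim9$signal,
                                      pipeline_config(estimated_cycle_s = 5)))
  expect_length(det9$segmentation$boundaries, 9)
  dd <- det9$segmentation$dd
  expect_gt(max(dd), 3 * median(dd))
})

test_that("segmentation is deterministic and bookkeeping is consistent", {
  sim <- generate_breathing(synth_spec(duration_s = 70, seed = 3))
  d1 <- suppressWarnings(cmw_detect(sim$signal, pipeline_config()))
  d2 <- suppressWarnings(cmw_detect(sim$signal, pipeline_config()))
  expect_identical(d1$segmentation$boundaries, d2$segmentation$boundaries)
  b <- d1$segmentation$boundaries
  expect_true(all(diff(b) > 0))
  expect_equal(d1$segmentation$dd, diff(b))
  rr <- d1$segmentation$rr_series
  expect_equal(sum(rr), sum(b < 60 * length(rr)))
})

test_that("brief loud clicks between cycles do not change the boundary count", {
  sim <- generate_breathing(synth_spec(duration_s = 80, cycle_period_s = 4,
                                       amplitude_jitter = 2, seed = 8))
  base <- suppressWarnings(cmw_detect(sim$signal, pipeline_config()))
  x <- sim$signal$samples
  fs <- sim$signal$sample_rate
  set.seed(99)
  clicks <- sim$truth$cycle_boundaries[c(4, 9, 14)] + 0.4
  for (tc in clicks) {
    i0 <- round(tc * fs)
    x[i0:(i0 + round(0.15 * fs))] <- max(abs(x)) * rnorm(round(0.15 * fs) + 1)
  }
  noisy <- suppressWarnings(cmw_detect(audio_signal(x, fs), pipeline_config()))
  expect_equal(length(noisy$segmentation$boundaries),
               length(base$segmentation$boundaries))
})

test_that("rr_per_minute uses half-open tumbling minutes", {
  expect_equal(as.vector(rr_per_minute(seq(0.5, 59.5, length.out = 14), 60)), 14)
  rr <- rr_per_minute(c(10, 60, 70), 120)
  expect_equal(as.vector(rr), c(1, 2))  # t = 60 counts in minute 2
  rr <- rr_per_minute(seq(1, 119, length.out = 28), 120)
  expect_equal(as.vector(rr), c(14, 14))
  # trailing partial minute reported separately, never scaled
  rr <- rr_per_minute(c(10, 20, 65), 90)
  expect_equal(as.vector(rr), 2)
  expect_equal(attr(rr, "partial"), 1)
  expect_equal(attr(rr, "partial_s"), 30)
  expect_error(rr_per_minute(c(-1, 10), 60), "within")
})

test_that("segmentation CSV export round-trips boundaries and RR", {
  sim <- generate_breathing(synth_spec(duration_s = 70, seed = 5))
  det <- suppressWarnings(cmw_detect(sim$signal, pipeline_config()))
  b_csv <- withr::local_tempfile(fileext = ".csv")
  r_csv <- withr::local_tempfile(fileext = ".csv")
  write_segmentation_csv(det$segmentation, b_csv, r_csv)
  b <- read.csv(b_csv)
  expect_equal(b$time_s, det$segmentation$boundaries)
  expect_equal(b$dd_s[-1], det$segmentation$dd)
  expect_equal(read.csv(r_csv)$rr, as.vector(det$segmentation$rr_series))
})
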