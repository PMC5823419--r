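test_that("cycle and boundary bookkeeping follows duration / period", {
  spec <- synth_spec(duration_s = 60, cycle_period_s = 4, cycle_jitter_cv = 0,
                     seed = 1)
  sim <- generate_breathing(spec)
  expect_length(sim$truth$cycle_boundaries, 15)
  expect_equal(nrow(sim$truth$events), 0)
  expect_length(sim$signal$samples, 60 * spec$sample_rate)
  expect_true(all(diff(sim$truth$cycle_boundaries) > 0))
})

test_that("scheduled pauses shift later cycles and are recorded", {
  spec <- synth_spec(duration_s = 60, cycle_period_s = 4, cycle_jitter_cv = 0,
                     apnea_schedule = data.frame(start_s = 20, gap_s = 15),
                     seed = 1)
  sim <- generate_breathing(spec)
  ev <- sim$truth$events
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "apnea")
  expect_equal(ev$start_s, 20)
  expect_equal(ev$gap_s, 15)
  # breathing halts for exactly gap_s: cycles fit in duration - gap
  expect_length(sim$truth$cycle_boundaries, floor((60 - 15) / 4))
  b <- sim$truth$cycle_boundaries
  expect_false(any(b > 20 & b < 35))
  # a sub-10 s gap is recorded as hypopnea
  spec2 <- synth_spec(duration_s = 40, apnea_schedule = data.frame(
    start_s = 12, gap_s = 7), seed = 1)
  expect_equal(generate_breathing(spec2)$truth$events$type, "hypopnea")
})

test_that("generation is bit-identical for a fixed seed", {
  spec <- synth_spec(duration_s = 30, seed = 42)
  a <- generate_breathing(spec)
  b <- generate_breathing(spec)
  expect_identical(a$signal$samples, b$signal$samples)
  expect_identical(a$truth$cycle_boundaries, b$truth$cycle_boundaries)
  c <- generate_breathing(synth_spec(duration_s = 30, seed = 43))
  expect_false(identical(a$signal$samples, c$signal$samples))
  # the global RNG stream is left untouched
  set.seed(7); before <- runif(1)
  set.seed(7); generate_breathing(spec); after <- runif(1)
  expect_identical(before, after)
})

test_that("spec invariants are validated", {
  expect_error(synth_spec(insp_dur_s = 0.2), "phase durations")
  expect_error(synth_spec(insp_dur_s = 1, exp_dur_s = 1, pause_dur_s = 2,
                          cycle_period_s = 3.5), "shorter than the cycle")
  expect_error(synth_spec(duration_s = 30, apnea_schedule = data.frame(
    start_s = 25, gap_s = 10)), "within")
  expect_error(synth_spec(amplitude_jitter = 0.5), "amplitude_jitter")
})

test_that("TCW has a local minimum at nearly every generated rest phase", {
  sim <- generate_breathing(synth_spec(duration_s = 120, seed = 12))
  proc <- preprocess(normalize_amplitude(sim$signal))
  sc <- scale_params(0.8, 0.1)
  tc <- tcw(proc, sc)
  mins <- tcw_minima(tc, sc)$time_s
  b <- sim$truth$cycle_boundaries
  b <- b[b > 2 & b < 118]
  hit <- vapply(b, function(t) any(abs(mins - t) <= 1), logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("success-rate metric matches greedy one-to-one matching", {
  truth <- c(10, 20, 30, 40)
  perfect <- evaluate_success_rate(truth, truth)
  expect_equal(perfect$success_rate, 100)
  expect_equal(perfect$false_positives, 0)

  # one miss, one false positive, one match just inside tolerance
  got <- evaluate_success_rate(c(10.9, 20, 55), truth, tol_s = 1)
  expect_equal(got$matched, 2)
  expect_equal(got$success_rate, 50)
  expect_equal(got$false_positives, 1)

  # each true boundary used at most once
  dup <- evaluate_success_rate(c(19.9, 20.1), truth, tol_s = 1)
  expect_equal(dup$matched, 1)
  expect_equal(dup$false_positives, 1)

  expect_error(evaluate_success_rate(1:3, numeric(0)), "no boundaries")
  expect_error(evaluate_success_rate(1:3, 1:3, tol_s = 0), "tol_s")
})

test_that("count-based success rate reproduces tabulated percentages", {
  expect_equal(success_rate(617, 663), 93.06)
  expect_equal(success_rate(100, 100), 100)
  expect_error(success_rate(10, 0), "manual_count")
})

test_that("ground-truth CSV export writes boundaries and events", {
  sim <- generate_breathing(synth_spec(duration_s = 50, apnea_schedule =
    data.frame(start_s = 20, gap_s = 12), seed = 3))
  b_csv <- withr::local_tempfile(fileext = ".csv")
  e_csv <- withr::local_tempfile(fileext = ".csv")
  write_truth_csv(sim$truth, b_csv, e_csv)
  expect_equal(read.csv(b_csv)$time_s, sim$truth$cycle_boundaries)
  expect_equal(read.csv(e_csv)$gap_s, 12)
})
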