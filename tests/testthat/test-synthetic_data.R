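test_that("survival generator reproduces the configured cohort moments", {
  # degenerate distribution
  expect_identical(gen_survival(5, 57, 0), rep(57, 5))
  # truncation bound respected for a spread of seeds
  for (s in 1:10) expect_gte(min(gen_survival(22, 57, 2, seed = s)), 22)
  # seeded sample mean within 3 SEM of the configured mean
  x <- gen_survival(22, 57, 2, seed = 101)
  expect_lt(abs(mean(x) - 57), 3 * 2)
  # deterministic given seed
  expect_identical(gen_survival(19, 77, 4, seed = 3), gen_survival(19, 77, 4, seed = 3))
  # >50% truncated mass is a configuration error
  expect_error(gen_survival(10, 21.9, 5), "below day 22")
})

test_that("mixture-weight calibration agrees with a quadrature oracle", {
  low <- c(620, 30); high <- c(770, 43); thr <- 684
  p_low <- pnorm(thr, low[1], low[2]); p_high <- pnorm(thr, high[1], high[2])
  expect_equal(calibrate_mixture_weight(p_high, thr, low, high), 0)
  expect_equal(calibrate_mixture_weight(p_low, thr, low, high), 1)
  w <- calibrate_mixture_weight(0.457, thr, low, high)
  expect_equal(oracle_mixture_mass(w, thr, low, high), 0.457, tolerance = 1e-6)
  # grid of reachable targets
  for (target in seq(0.05, 0.9, by = 0.05)) {
    w <- calibrate_mixture_weight(target, thr, low, high)
    expect_equal(oracle_mixture_mass(w, thr, low, high), target, tolerance = 1e-6)
  }
  expect_error(calibrate_mixture_weight(0.995, thr, low, high), "attainable range")
  expect_error(calibrate_mixture_weight(0.3, thr, high, low), "below-threshold mass")
})

test_that("ECG segment generator matches the wild-type Gaussian", {
  seg <- gen_ecg_segments(20000, mixture_weight = 0, noise_fraction = 0, seed = 5)
  # ~95% of WT draws within [684, 856] = mean +/- 2 SD
  expect_equal(mean(seg$mean_hr >= 684 & seg$mean_hr <= 856), 0.954, tolerance = 0.01)
  # below-threshold tail of the pure high component ~ Phi(-2)
  expect_equal(mean(seg$mean_hr < 684), pnorm(-2), tolerance = 0.15)
  all_noisy <- gen_ecg_segments(50, noise_fraction = 1, seed = 2)
  expect_true(all(all_noisy$noisy))
  expect_true(all(seg$n_beats >= 25 & seg$n_beats <= 75))
})

test_that("airflow generator injects ground-truth apneas faithfully", {
  spec <- data.frame(onset_s = 30, n_cycles = 3, depth = 0.95)
  tr <- gen_airflow(120, 120, apnea_spec = spec, seed = 4)
  expect_identical(nrow(tr$ground_truth), 1L)
  expect_true(tr$ground_truth$meets_definition)
  sub <- gen_airflow(120, 120,
                     apnea_spec = data.frame(onset_s = 30, n_cycles = 3, depth = 0.5),
                     seed = 4)
  expect_false(sub$ground_truth$meets_definition)
  short <- gen_airflow(120, 120,
                       apnea_spec = data.frame(onset_s = 30, n_cycles = 1.5, depth = 0.95),
                       seed = 4)
  expect_false(short$ground_truth$meets_definition)
  overlap <- data.frame(onset_s = c(30, 30.5), n_cycles = c(4, 4), depth = 0.95)
  expect_error(gen_airflow(120, 120, apnea_spec = overlap), "overlap")
})

test_that("SpO2 generator hits its calibrated mean and hypoxemia fraction", {
  wt <- gen_spo2_stream(4000, 5, target_mean = 96.48, target_hypox_fraction = 0,
                        error_rate = 0, seed = 8)
  expect_identical(nrow(filter_error_free(wt)), nrow(wt))
  expect_equal(mean(wt$sao2_pct), 96.48, tolerance = 0.01)
  expect_identical(sum(wt$sao2_pct < 90), 0L)

  ko <- gen_spo2_stream(8000, 5, target_mean = 90.05, target_hypox_fraction = 0.33,
                        error_rate = 0, seed = 9)
  expect_equal(mean(ko$sao2_pct < 90), 0.33, tolerance = 0.015)
  expect_equal(mean(ko$sao2_pct), 90.05, tolerance = 0.05)

  dead <- gen_spo2_stream(100, 5, error_rate = 1, seed = 2)
  expect_identical(nrow(filter_error_free(dead)), 0L)

  # realized error-free fraction tracks 1 - error_rate (binomial 3 SE band)
  st <- gen_spo2_stream(3600, 5, target_mean = 96.48, error_rate = 0.94, seed = 3)
  n <- nrow(st)
  frac <- nrow(filter_error_free(st)) / n
  expect_lt(abs(frac - 0.06), 3 * sqrt(0.06 * 0.94 / n))
  # unreachable mean/fraction pair
  expect_error(gen_spo2_stream(100, 5, target_mean = 99.9,
                               target_hypox_fraction = 0.5), "unreachable")
})

test_that("EEG/EMG generator produces epoch-aligned ground truth", {
  ee <- gen_eeg_emg(600, sample_rate_hz = 100, seed = 6)
  expect_identical(nrow(ee$ground_truth), 60L)
  expect_identical(length(ee$eeg), 60L * 1000L)
  all_wake <- gen_eeg_emg(300, occupancy = c(wake = 1, nrem = 0, rem = 0),
                          sample_rate_hz = 100, seed = 2)
  expect_true(all(all_wake$ground_truth$state == "WAKE"))
  expect_error(gen_eeg_emg(300, occupancy = c(wake = 0.6, nrem = 0.6, rem = 0.1),
                           sample_rate_hz = 100), "sum to 1")
  expect_error(gen_eeg_emg(305, sample_rate_hz = 100), "multiple")
  # seizure epochs flagged and energetic
  sz <- gen_eeg_emg(300, seizure_epochs = c(5L, 6L), sample_rate_hz = 100, seed = 2)
  expect_identical(which(sz$ground_truth$seizure), c(5L, 6L))
  # determinism given (config, seed); different seed changes draws
  a <- gen_eeg_emg(300, sample_rate_hz = 100, seed = 7)
  b <- gen_eeg_emg(300, sample_rate_hz = 100, seed = 7)
  c <- gen_eeg_emg(300, sample_rate_hz = 100, seed = 8)
  expect_identical(a$eeg, b$eeg)
  expect_false(identical(a$eeg, c$eeg))
})

test_that("random apnea specs are non-overlapping and in range", {
  set.seed(12)
  for (i in 1:20) {
    spec <- gen_apnea_spec(rpois(1, 6.3) + 1L, 180, 120, seed = new_seeds(1))
    if (is.null(spec)) next
    period <- 60 / 120
    ends <- spec$onset_s + spec$n_cycles * period
    expect_true(all(spec$onset_s >= 0) && all(ends <= 180))
    if (nrow(spec) > 1) expect_true(all(spec$onset_s[-1] >= ends[-nrow(spec)]))
  }
})
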