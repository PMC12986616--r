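test_that("the two-cycle window converts breath rate to seconds", {
  expect_equal(two_cycle_window(120), 1)
  expect_equal(two_cycle_window(60), 2)
  expect_lt(two_cycle_window(1e6), 1e-3)
  expect_error(two_cycle_window(0), "positive")
  expect_error(two_cycle_window(-10), "positive")
})

test_that("breath rate is recoverable from the eupneic trace", {
  tr <- gen_airflow(60, 120, seed = 2)
  expect_equal(estimate_breath_rate(tr$flow, tr$sample_rate_hz), 120, tolerance = 0.05)
})

test_that("the detector finds injected apneas and rejects shallow or short ones", {
  # constant-amplitude breathing: no events
  quiet <- gen_airflow(120, 120, seed = 3)
  expect_identical(nrow(detect_apneas(quiet)), 0L)
  # one 95%-depth, 3-cycle pause: exactly one event
  one <- gen_airflow(120, 120,
                     apnea_spec = data.frame(onset_s = 40, n_cycles = 3, depth = 0.95),
                     seed = 3)
  ev <- detect_apneas(one)
  expect_identical(nrow(ev), 1L)
  expect_gte(ev$depth, 0.90)
  expect_equal(ev$onset_s, 40, tolerance = 1)
  # a 1.5-cycle pause fails the duration criterion
  short <- gen_airflow(120, 120,
                       apnea_spec = data.frame(onset_s = 40, n_cycles = 1.5, depth = 0.95),
                       seed = 3)
  expect_identical(nrow(detect_apneas(short)), 0L)
  # a 50%-depth drop fails the amplitude criterion
  shallow <- gen_airflow(120, 120,
                         apnea_spec = data.frame(onset_s = 40, n_cycles = 4, depth = 0.5),
                         seed = 3)
  expect_identical(nrow(detect_apneas(shallow)), 0L)
  expect_error(detect_apneas(gen_airflow(3, 120, seed = 1)), "shorter than")
})

test_that("sensitivity and specificity against generator ground truth", {
  set.seed(14)
  for (i in 1:15) {
    n_deep <- sample(1:4, 1)
    spec <- gen_apnea_spec(n_deep, 180, 120, depth_range = c(0.95, 0.99),
                           cycles_range = c(3L, 5L), seed = new_seeds(1))
    tr <- gen_airflow(180, 120, apnea_spec = spec, seed = new_seeds(1))
    ev <- detect_apneas(tr)
    expect_identical(nrow(ev), nrow(tr$ground_truth))
    # every detected event matches an injected onset
    for (k in seq_len(nrow(ev))) {
      expect_true(any(abs(ev$onset_s[k] - tr$ground_truth$onset_s) < 1.5))
    }
    # shallow events are never reported
    sh <- gen_apnea_spec(2, 180, 120, depth_range = c(0.3, 0.5), seed = new_seeds(1))
    tr_sh <- gen_airflow(180, 120, apnea_spec = sh, seed = new_seeds(1))
    expect_identical(nrow(detect_apneas(tr_sh)), 0L)
  }
})

test_that("detector equals the exhaustive interval oracle on short traces", {
  set.seed(6)
  for (i in 1:30) {
    n_ev <- sample(0:3, 1)
    spec <- gen_apnea_spec(n_ev, 60, 120, depth_range = c(0.5, 0.99),
                           cycles_range = c(1L, 5L), seed = new_seeds(1))
    tr <- gen_airflow(60, 120, sample_rate_hz = 50, apnea_spec = spec,
                      seed = new_seeds(1))  # 3000 samples
    ev <- detect_apneas(tr)
    oracle <- oracle_apnea_intervals(tr$flow, 50, 120)
    expect_identical(nrow(ev), length(oracle))
    for (k in seq_along(oracle)) {
      expect_equal(ev$onset_s[k], (oracle[[k]]["start"] - 1) / 50,
                   tolerance = 1e-9, ignore_attr = TRUE)
      expect_equal(ev$duration_s[k],
                   (oracle[[k]]["end"] - oracle[[k]]["start"] + 1) / 50,
                   tolerance = 1e-9, ignore_attr = TRUE)
    }
    # events never overlap and are ordered
    if (nrow(ev) > 1) {
      expect_true(all(ev$onset_s[-1] >= (ev$onset_s + ev$duration_s)[-nrow(ev)]))
    }
  }
})

test_that("counts and susceptibility aggregate per subject and bin", {
  expect_identical(apnea_count(data.frame()), 0L)
  ev <- data.frame(onset_s = c(1, 5, 9), duration_s = 1, depth = 0.95)
  expect_identical(apnea_count(ev), 3L)
  expect_identical(susceptibility(list(a = c(0, 0), b = c(0, 1), c = 3)),
                   c(a = FALSE, b = TRUE, c = TRUE))
  expect_equal(mean(susceptibility(list(c(0, 0), c(0, 0)))), 0)
  expect_error(susceptibility(list(a = integer(0))), "at least one session")
})
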