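test_that("PTD alignment matches the worked session schedules", {
  # death the day after the session
  expect_identical(compute_ptd(56, 57), 1L)
  # death 5 days after the fourth session: 5, 15, 25, 35 days PTD
  expect_identical(compute_ptd(c(65, 55, 45, 35), 70), c(5L, 15L, 25L, 35L))
  expect_identical(compute_ptd(47, 57), 10L)
  expect_error(compute_ptd(60, 57, subject_id = "KO-1"), "KO-1")
  expect_error(compute_ptd(57, 57), "death day itself")
})

test_that("10-day binning uses closed integer ranges", {
  expect_identical(bin_ptd(c(1L, 10L)), c(1L, 1L))
  expect_identical(bin_ptd(11L), 2L)
  expect_identical(bin_ptd(35L), 4L)
  expect_error(bin_ptd(0L))
  expect_error(bin_ptd(-3L))
  # monotone non-decreasing in ptd
  ptd <- 1:200
  expect_true(all(diff(bin_ptd(ptd)) >= 0))
  # compute_ptd inverts death_day - ptd on valid days
  expect_identical(compute_ptd(77 - ptd, 77), ptd)
})

test_that("pooling by bin is a partition of the input frames", {
  mk <- function(ptd, n = length(ptd)) {
    data.frame(subject_id = sprintf("s%d", seq_len(n)), genotype = rep("KO", n),
               diet = rep("SD", n), ptd = ptd, value = rnorm(n),
               endpoint_name = rep("apnea_count", n))
  }
  expect_identical(nrow(pool_by_bin(mk(integer(0), 0))), 0L)
  p <- pool_by_bin(mk(c(1L, 10L, 11L)))
  expect_identical(as.vector(table(p$group)), c(2L, 1L))
  doubled <- pool_by_bin(rbind(mk(c(1L, 10L, 11L)), mk(c(1L, 10L, 11L))))
  expect_identical(as.vector(table(doubled$group)), c(4L, 2L))
  mixed <- mk(c(1L, 2L))
  mixed$endpoint_name <- c("a", "b")
  expect_error(pool_by_bin(mixed), "mix endpoints")

  # partition property on random frames: every row in exactly one group
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(1:60, 1)
    f <- data.frame(
      subject_id = sample(letters, n, replace = TRUE),
      genotype = sample(c("WT", "KO"), n, replace = TRUE),
      diet = sample(c("SD", "KD"), n, replace = TRUE),
      ptd = sample(1:45, n, replace = TRUE),
      value = rnorm(n), endpoint_name = "burden"
    )
    p <- pool_by_bin(f)
    expect_identical(nrow(p), n)
    expect_identical(sum(table(p$group)), n)
    expect_true(all(p$bin_index == ceiling(p$ptd / 10)))
  }
})

test_that("manifest validation enforces the littermate-pairing rules", {
  m <- data.frame(
    subject_id = c("KO-1", "WT-1"), genotype = c("KO", "WT"),
    diet = "SD", sex = c("M", "F"), death_day = c(57L, 57L),
    paired_littermate = c("WT-1", "KO-1")
  )
  expect_silent(validate_manifest(m))
  m_bad <- m; m_bad$death_day[2] <- 60L
  expect_error(validate_manifest(m_bad), "share death_day")
  m_na <- m; m_na$death_day[1] <- NA
  expect_error(validate_manifest(m_na), "required for KO")
  m_young <- m; m_young$death_day <- c(20L, 20L)
  expect_error(validate_manifest(m_young), "weaning")
})

test_that("manifests round-trip through CSV and JSON", {
  m <- data.frame(
    subject_id = c("KO-1", "WT-1"), genotype = c("KO", "WT"),
    diet = c("KD", "KD"), sex = c("M", "F"), death_day = c(77L, 77L),
    paired_littermate = c("WT-1", "KO-1")
  )
  csv <- tempfile(fileext = ".csv"); json <- tempfile(fileext = ".json")
  write_manifest(m, csv); write_manifest(m, json)
  expect_identical(read_manifest(csv), m)
  expect_identical(read_manifest(json), m)
})

test_that("session tables are validated against the manifest", {
  m <- data.frame(subject_id = "KO-1", genotype = "KO", diet = "SD",
                  sex = "M", death_day = 57L)
  s <- data.frame(subject_id = "KO-1", modality = "ECG",
                  record_day = c(36L, 46L, 56L), duration_s = 300)
  expect_silent(validate_sessions(s, m))
  s_late <- s; s_late$record_day[3] <- 58L
  expect_error(validate_sessions(s_late, m), "after death_day")
  s_dup <- s; s_dup$record_day <- c(36L, 36L, 56L)
  expect_error(validate_sessions(s_dup, m), "strictly increasing")
})
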