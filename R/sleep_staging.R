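# Mean periodogram power of each epoch (columns of `m`) in [f_lo, f_hi],
# Hann-tapered. Absolute scale is irrelevant downstream (staging works on
# log-standardized features); zero signal maps to zero power.
epoch_band_power <- function(m, fs, f_lo, f_hi) {
  n <- nrow(m)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  X <- mvfft(m * w)
  freq <- (seq_len(n) - 1) * fs / n
  keep <- freq >= f_lo & freq <= f_hi & freq <= fs / 2
  if (!any(keep)) stop_domain("band power: no Fourier bin falls in [%g, %g] Hz", f_lo, f_hi)
  colMeans(abs(X[keep, , drop = FALSE])^2) / (fs * sum(w^2))
}

#' Per-epoch delta-band and EMG-band power
#'
#' Divides paired EEG and EMG traces into consecutive epochs (default 10 s;
#' a trailing partial epoch is dropped) and computes, per epoch, the mean
#' Hann-tapered periodogram power of the EEG in the delta band (0.5-4 Hz) and
#' of the EMG in 10-50 Hz.
#'
#' @param eeg,emg Numeric traces of equal length.
#' @param sample_rate_hz Sampling rate of both traces.
#' @param epoch_s Epoch length, seconds.
#' @param delta_band,emg_band Numeric `c(lo, hi)` Hz.
#' @return Data frame: `epoch`, `delta_power`, `emg_power`.
#' @export
epoch_features <- function(eeg, emg, sample_rate_hz, epoch_s = 10,
                           delta_band = c(0.5, 4), emg_band = c(10, 50)) {
  if (length(eeg) != length(emg)) {
    stop_domain("epoch_features: EEG and EMG traces differ in length (%d vs %d)",
                length(eeg), length(emg))
  }
  n_per <- as.integer(round(epoch_s * sample_rate_hz))
  n_epochs <- length(eeg) %/% n_per
  if (n_epochs < 1L) stop_domain("epoch_features: trace shorter than one epoch")
  used <- n_epochs * n_per
  eeg_m <- matrix(eeg[seq_len(used)], nrow = n_per)
  emg_m <- matrix(emg[seq_len(used)], nrow = n_per)
  emg_hi <- min(emg_band[2], sample_rate_hz / 2)
  data.frame(
    epoch = seq_len(n_epochs),
    delta_power = epoch_band_power(eeg_m, sample_rate_hz, delta_band[1], delta_band[2]),
    emg_power = epoch_band_power(emg_m, sample_rate_hz, emg_band[1], emg_hi)
  )
}

# Deterministic seeded farthest-point initialization for 3-means: first
# center is a seeded random point, each next center maximizes the minimal
# distance to those already chosen.
farthest_point_centers <- function(x, k, seed) {
  idx <- with_seed(seed, sample.int(nrow(x), 1))
  for (j in seq_len(k - 1L)) {
    d <- vapply(seq_len(nrow(x)), function(i) {
      min(colSums((t(x[idx, , drop = FALSE]) - x[i, ])^2))
    }, 0)
    idx <- c(idx, which.max(d))
  }
  x[idx, , drop = FALSE]
}

#' Segregate epochs into wake, NREM and REM
#'
#' Features (delta power, EMG power) are log-transformed and standardized,
#' projected on their principal components, and partitioned into three
#' clusters by k-means with a seeded farthest-point initialization. Clusters
#' are mapped to vigilance states by the band-power rule: the cluster with
#' the highest mean delta power is NREM; of the remaining two, the one with
#' higher mean EMG power is wake, the other REM (wake = low delta/high EMG,
#' NREM = high delta, REM = low delta/low EMG). The mapping is rule-based,
#' so the result is invariant to cluster label permutation.
#'
#' @param features Data frame from [epoch_features()]; rows flagged in
#'   `exclude` are ignored for fitting and labelled `EXCLUDED`.
#' @param exclude Optional logical vector marking epochs to leave out.
#' @param seed RNG seed for the initialization.
#' @return Character vector of states per epoch
#'   (`WAKE`/`NREM`/`REM`/`EXCLUDED`).
#' @export
classify_states <- function(features, exclude = NULL, seed = 1L) {
  stopifnot(all(c("delta_power", "emg_power") %in% names(features)))
  n <- nrow(features)
  exclude <- exclude %||% rep(FALSE, n)
  use <- !exclude
  if (sum(use) < 3L) stop_domain("classify_states: need at least 3 analyzable epochs")
  f <- cbind(log(pmax(features$delta_power[use], .Machine$double.xmin)),
             log(pmax(features$emg_power[use], .Machine$double.xmin)))
  if (any(apply(f, 2, sd) < 1e-12)) {
    stop_domain("classify_states: degenerate feature variance; stage this recording manually")
  }
  z <- scale(f)
  pc <- prcomp(z, center = FALSE, scale. = FALSE)$x
  centers <- farthest_point_centers(pc, 3L, seed)
  km <- kmeans(pc, centers = centers, iter.max = 100)
  cl <- km$cluster
  mean_delta <- tapply(features$delta_power[use], cl, mean)
  nrem_cl <- as.integer(names(which.max(mean_delta)))
  rest <- setdiff(sort(unique(cl)), nrem_cl)
  mean_emg <- tapply(features$emg_power[use], cl, mean)
  wake_cl <- rest[which.max(mean_emg[as.character(rest)])]
  rem_cl <- setdiff(rest, wake_cl)
  map <- setNames(character(3), c(nrem_cl, wake_cl, rem_cl))
  map[as.character(nrem_cl)] <- "NREM"
  map[as.character(wake_cl)] <- "WAKE"
  map[as.character(rem_cl)] <- "REM"
  out <- rep("EXCLUDED", n)
  out[use] <- unname(map[as.character(cl)])
  out
}

#' Exclude epochs overlapping seizure or husbandry-check intervals
#'
#' Any epoch that overlaps a seizure interval, or a veterinary/husbandry
#' check interval, is removed from sleep-architecture analysis and labelled
#' `EXCLUDED` with its reason.
#'
#' @param states Character state vector (one per epoch).
#' @param seizure_intervals,check_intervals Data frames with `onset_s`,
#'   `duration_s` in session time, or `NULL`.
#' @param epoch_s Epoch length, seconds.
#' @return Data frame: `epoch`, `state`, `exclusion_reason` (`NA`, `SEIZURE`
#'   or `CHECK`).
#' @export
apply_exclusions <- function(states, seizure_intervals = NULL,
                             check_intervals = NULL, epoch_s = 10) {
  n <- length(states)
  reason <- rep(NA_character_, n)
  mark <- function(intervals, label) {
    if (is.null(intervals) || nrow(intervals) == 0L) return()
    for (i in seq_len(nrow(intervals))) {
      lo <- intervals$onset_s[i]
      hi <- lo + intervals$duration_s[i]
      first <- max(1L, floor(lo / epoch_s) + 1L)
      last <- min(n, ceiling(hi / epoch_s))
      if (hi %% epoch_s == 0 && hi / epoch_s <= n) last <- min(n, as.integer(hi / epoch_s))
      if (first <= last) reason[first:last] <<- label
    }
  }
  mark(check_intervals, "CHECK")
  mark(seizure_intervals, "SEIZURE")
  states[!is.na(reason)] <- "EXCLUDED"
  data.frame(epoch = seq_len(n), state = states, exclusion_reason = reason)
}

#' Vigilance-state occupancy
#'
#' Fractions of wake, NREM and REM epochs, normalized to the number of
#' analyzed (non-excluded) epochs, so the three fractions sum to 1.
#'
#' @param states Character vector of per-epoch states, or the data frame
#'   returned by [apply_exclusions()].
#' @return Named numeric `c(wake, nrem, rem)`.
#' @export
occupancy <- function(states) {
  if (is.data.frame(states)) states <- states$state
  analyzed <- states[states != "EXCLUDED"]
  if (!length(analyzed)) stop_domain("occupancy: no analyzable epochs (all excluded)")
  c(
    wake = mean(analyzed == "WAKE"),
    nrem = mean(analyzed == "NREM"),
    rem = mean(analyzed == "REM")
  )
}
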