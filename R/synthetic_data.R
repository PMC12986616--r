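#' Default synthetic-study configuration
#'
#' Returns the study conditions used by every generator: cohort survival
#' parameters, the wild-type heart-rate Gaussian, per-cohort-and-bin targets
#' for bradycardic fraction, SaO2 mean and hypoxemia fraction, apnea rates,
#' breathing rate, sleep-state occupancies and state-conditional feature
#' distributions, epoch length and sampling rates. Defaults mirror the
#' reported cohort summary statistics of the source study (KO-SD survival
#' 57 +/- 2 SEM over n = 22; KO-KD 77 +/- 4 over n = 19; WT heart rate
#' 770 +/- 43 bpm SD; bradycardia threshold at mean - 2 SD; KO-SD bin-1
#' bradycardic fraction 0.457 vs WT-SD 0.072; KO-SD SaO2 mean 90.05% in
#' bin 1 and 93.92% in bin 2 vs pooled WT 96.48%; KO-SD bin-1 hypoxemia
#' fraction 0.33; KO-SD apnea rate 6.3 episodes/session in bin 1 and 0.8 in
#' bin 3).
#'
#' @param ... Named overrides merged over the defaults (one level deep).
#' @return A list of class `study_config`.
#' @export
study_config <- function(...) {
  cfg <- list(
    survival = list(
      KO_SD = list(n = 22L, mean = 57, sem = 2),
      KO_KD = list(n = 19L, mean = 77, sem = 4)
    ),
    wt_hr = list(mean = 770, sd = 43),
    hr_low = list(mean = 620, sd = 30),          # bradycardic mixture component
    brady_fraction = list(                        # below-threshold target by cohort/bin
      KO_SD = c(`1` = 0.457, `2` = 0.457),
      WT_SD = c(`1` = 0.072, `2` = 0.072),
      KO_KD = c(`1` = 0.072, `2` = 0.072),
      WT_KD = c(`1` = 0.072, `2` = 0.072)
    ),
    segments_per_session = 16L,
    segment_noise_fraction = 0.1,
    spo2 = list(
      low = list(mean = 85, sd = 3),              # hypoxemic dip component
      base_sd = 1.2,
      rate_hz = 5,
      session_s = 3600,
      # 1 h at 5 Hz = 18,000 nominal samples; a 94% per-sample failure rate
      # leaves ~1,080 error-free measurements, inside the reported 507-1530
      # per-subject range
      error_rate = 0.94,
      targets = list(                             # mean %, hypoxemia fraction
        KO_SD = list(`1` = c(90.05, 0.33), `2` = c(93.92, 0.10)),
        KO_KD = list(`1` = c(95.13, 0.02), `2` = c(96.83, 0.005)),
        WT    = list(`1` = c(96.48, 0.0),  `2` = c(96.48, 0.0))
      )
    ),
    apnea_rate = list(                            # mean episodes per 3-min session
      KO_SD = c(`1` = 6.3, `2` = 2.0, `3` = 0.8),
      KO_KD = c(`1` = 1.0, `2` = 1.0, `3` = 2.6),
      WT_SD = c(`1` = 0.1, `2` = 0.1, `3` = 0.1),
      WT_KD = c(`1` = 0.2, `2` = 0.2, `3` = 0.2)
    ),
    breath_rate = 120,                            # breaths/min eupnea
    airflow_rate_hz = 100,
    airflow_session_s = 180,
    seizure = list(
      # mean seizures per 48 h session (99 events / 12 KO-SD sessions;
      # 68 / 20 KO-KD sessions; none in WT)
      rate = c(KO_SD = 99 / 12, KO_KD = 68 / 20, WT_SD = 0, WT_KD = 0),
      duration_meanlog = log(40), duration_sdlog = 0.4,
      severity_probs = c(0.15, 0.2, 0.2, 0.15, 0.15, 0.15)
    ),
    sleep = list(
      occupancy = c(wake = 0.45, nrem = 0.45, rem = 0.10),
      # state-conditional band powers, lognormal (meanlog, sdlog)
      delta = list(wake = c(log(1), 0.2), nrem = c(log(10), 0.2), rem = c(log(1), 0.2)),
      emg   = list(wake = c(log(10), 0.2), nrem = c(log(2), 0.2), rem = c(log(0.3), 0.2)),
      epoch_s = 10,
      window_s = 7 * 3600                          # sleep-phase window ZT1-ZT8
    ),
    eeg_rate_hz = 2000,
    spo2_rate_hz = 5,
    seed = 1L
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  bad <- function(x) any(!is.finite(x)) || any(x < 0)
  occ <- cfg$sleep$occupancy
  if (abs(sum(occ) - 1) > 1e-9) stop_domain("study_config: sleep occupancies must sum to 1")
  for (co in names(cfg$survival)) {
    s <- cfg$survival[[co]]
    if (s$n < 2 || s$mean <= 21 || s$sem <= 0) {
      stop_domain("study_config: invalid survival parameters for %s", co)
    }
  }
  if (cfg$wt_hr$sd <= 0 || cfg$hr_low$sd <= 0) stop_domain("study_config: heart-rate SDs must be > 0")
  for (co in names(cfg$brady_fraction)) {
    if (bad(cfg$brady_fraction[[co]]) || any(cfg$brady_fraction[[co]] > 1)) {
      stop_domain("study_config: bradycardic fractions must lie in [0, 1]")
    }
  }
  structure(cfg, class = "study_config")
}

#' Generate cohort survival times
#'
#' Ages at sudden death are drawn from a normal distribution with the cohort
#' mean and SD = SEM * sqrt(n) (the minimal model reproducing the reported
#' mean +/- SEM), truncated below at day 22 (no death before weaning) and
#' rounded to whole postnatal days.
#'
#' @param n Number of subjects (>= 2).
#' @param mean Cohort mean age at death, postnatal days (> 21).
#' @param sem Standard error of the cohort mean, days.
#' @param seed RNG seed.
#' @return Integer vector of `n` ages at death (days), all >= 22.
#' @export
gen_survival <- function(n, mean, sem, seed = 1L) {
  stopifnot(n >= 2, mean > 21, sem >= 0)
  if (sem == 0) return(rep(round(mean), n))
  sdv <- sem * sqrt(n)
  p_trunc <- pnorm(22, mean, sdv)
  if (p_trunc > 0.5) {
    stop_domain(
      "gen_survival: parameters put %.0f%% of mass below day 22; choose a larger mean or smaller sem",
      100 * p_trunc
    )
  }
  with_seed(seed, {
    u <- runif(n, p_trunc, 1)
    as.integer(round(qnorm(u, mean, sdv)))
  })
}

#' Calibrate a two-component mixture weight to a below-threshold mass
#'
#' Finds the weight `w` on the low component such that the mixture
#' `w * N(low) + (1 - w) * N(high)` has exactly `target_fraction` of its mass
#' below `threshold`. Because the below-threshold probability is linear in
#' `w`, the solution is closed-form; it is an error if the target lies outside
#' the attainable range `[P(high < thr), P(low < thr)]`.
#'
#' @param target_fraction Target below-threshold probability in \[0, 1\].
#' @param threshold Classification threshold, in the units of the components.
#' @param low,high Numeric `c(mean, sd)` of the two Gaussian components; the
#'   low component must place more mass below the threshold than the high one.
#' @return Mixing weight on the low component, clipped to \[0, 1\].
#' @examples
#' # KO-SD bin-1 bradycardic target below the 684-bpm threshold
#' calibrate_mixture_weight(0.457, 684, low = c(620, 30), high = c(770, 43))
#' @export
calibrate_mixture_weight <- function(target_fraction, threshold, low, high) {
  stopifnot(length(low) == 2, length(high) == 2, low[2] > 0, high[2] > 0)
  p_low <- pnorm(threshold, low[1], low[2])
  p_high <- pnorm(threshold, high[1], high[2])
  if (p_low <= p_high) {
    stop_domain("calibrate_mixture_weight: low component must have more below-threshold mass than high")
  }
  if (target_fraction < p_high - 1e-12 || target_fraction > p_low + 1e-12) {
    stop_domain(
      "calibrate_mixture_weight: target %.4f unreachable; attainable range is [%.4f, %.4f]",
      target_fraction, p_high, p_low
    )
  }
  min(1, max(0, (target_fraction - p_high) / (p_low - p_high)))
}

#' Generate ECG segment mean heart rates for one session
#'
#' Emulates the screening workflow: a session yields ~16 segments of 25-75
#' P-Q-R-S-T complexes; a configurable fraction is flagged noisy (excluded
#' downstream); clean segment mean rates are drawn from the calibrated
#' bradycardic/normal Gaussian mixture. With `mixture_weight = 0` all draws
#' come from the wild-type Gaussian.
#'
#' @param n_segments Number of segments (default 16).
#' @param mixture_weight Weight on the bradycardic (low) component.
#' @param high,low Numeric `c(mean, sd)` for normal and bradycardic rates
#'   (bpm).
#' @param noise_fraction Probability a segment is flagged noisy.
#' @param seed RNG seed.
#' @return Data frame: `segment`, `n_beats`, `mean_hr`, `noisy`.
#' @export
gen_ecg_segments <- function(n_segments = 16L, mixture_weight = 0,
                             high = c(770, 43), low = c(620, 30),
                             noise_fraction = 0, seed = 1L) {
  stopifnot(n_segments >= 1, mixture_weight >= 0, mixture_weight <= 1,
            noise_fraction >= 0, noise_fraction <= 1)
  with_seed(seed, {
    from_low <- runif(n_segments) < mixture_weight
    hr <- ifelse(from_low,
                 rnorm(n_segments, low[1], low[2]),
                 rnorm(n_segments, high[1], high[2]))
    data.frame(
      segment = seq_len(n_segments),
      n_beats = sample(25:75, n_segments, replace = TRUE),
      mean_hr = hr,
      noisy = runif(n_segments) < noise_fraction
    )
  })
}

#' Generate a synthetic airflow trace with injected apneas
#'
#' A quasi-sinusoidal breath train at the eupneic rate with per-breath
#' amplitude jitter and small additive sensor noise. Within each injected
#' apnea interval the breathing envelope is scaled by `1 - depth`, so a depth
#' of 0.95 leaves 5% residual airflow. Injected events are returned as ground
#' truth with a flag for whether each meets the operational apnea definition
#' (depth >= 0.90 for at least two complete respiratory cycles).
#'
#' @param duration_s Trace duration, seconds.
#' @param breath_rate Breaths per minute.
#' @param apnea_spec Data frame with columns `onset_s`, `n_cycles`, `depth`
#'   (fractional decrease in \[0, 1\]); intervals must fit in the trace and not
#'   overlap. `NULL` for none.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param amp_jitter_sd SD of per-breath amplitude jitter (baseline 1).
#' @param noise_sd SD of additive broadband noise.
#' @param seed RNG seed.
#' @return List: `t` (s), `flow`, `sample_rate_hz`, `breath_rate`, and
#'   `ground_truth` (onset_s, duration_s, depth, meets_definition).
#' @export
gen_airflow <- function(duration_s, breath_rate, apnea_spec = NULL,
                        sample_rate_hz = 100, amp_jitter_sd = 0.05,
                        noise_sd = 0.005, seed = 1L) {
  stopifnot(duration_s > 0, breath_rate > 0, sample_rate_hz > 0)
  period <- 60 / breath_rate
  n <- floor(duration_s * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz
  if (!is.null(apnea_spec) && nrow(apnea_spec) > 0) {
    apnea_spec <- apnea_spec[order(apnea_spec$onset_s), , drop = FALSE]
    dur <- apnea_spec$n_cycles * period
    ends <- apnea_spec$onset_s + dur
    if (any(apnea_spec$onset_s < 0) || any(ends > duration_s)) {
      stop_domain("gen_airflow: apnea interval outside the trace")
    }
    if (nrow(apnea_spec) > 1 && any(apnea_spec$onset_s[-1] < ends[-length(ends)])) {
      stop_domain("gen_airflow: apnea intervals overlap")
    }
    if (any(apnea_spec$depth < 0 | apnea_spec$depth > 1)) {
      stop_domain("gen_airflow: apnea depth must lie in [0, 1]")
    }
  }
  with_seed(seed, {
    n_cycles_tot <- ceiling(duration_s / period) + 1L
    amp_per_cycle <- pmax(0.2, rnorm(n_cycles_tot, 1, amp_jitter_sd))
    cycle_of_t <- pmin(n_cycles_tot, floor(t / period) + 1L)
    amp <- amp_per_cycle[cycle_of_t]
    scale <- rep(1, n)
    gt <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                     depth = numeric(0), meets_definition = logical(0))
    if (!is.null(apnea_spec) && nrow(apnea_spec) > 0) {
      for (i in seq_len(nrow(apnea_spec))) {
        on <- apnea_spec$onset_s[i]
        du <- apnea_spec$n_cycles[i] * period
        idx <- t >= on & t < on + du
        scale[idx] <- 1 - apnea_spec$depth[i]
      }
      gt <- data.frame(
        onset_s = apnea_spec$onset_s,
        duration_s = apnea_spec$n_cycles * period,
        depth = apnea_spec$depth,
        meets_definition = apnea_spec$depth >= 0.90 & apnea_spec$n_cycles >= 2
      )
    }
    flow <- amp * scale * sin(2 * pi * t / period) + rnorm(n, 0, noise_sd)
    list(t = t, flow = flow, sample_rate_hz = sample_rate_hz,
         breath_rate = breath_rate, ground_truth = gt)
  })
}

# Joint calibration of the SaO2 mixture: the hypoxemic-dip component is fixed
# (default mean 85, SD 3, clearly beyond the 90% demarcation); the baseline
# mean is tied to the weight by the overall-mean constraint, and the weight is
# solved so the below-90 mass equals the target fraction.
spo2_mixture_params <- function(target_mean, target_hypox_fraction,
                                low = c(85, 3), base_sd = 1.2, threshold = 90) {
  stopifnot(target_mean > 50, target_mean <= 100,
            target_hypox_fraction >= 0, target_hypox_fraction < 1)
  if (target_hypox_fraction == 0) {
    return(list(w = 0, base_mean = target_mean))
  }
  f <- function(w) {
    base_mean <- (target_mean - w * low[1]) / (1 - w)
    w * pnorm(threshold, low[1], low[2]) +
      (1 - w) * pnorm(threshold, base_mean, base_sd) - target_hypox_fraction
  }
  # keep the implied baseline mean at or below 99% so the cap at 100 stays
  # negligible: (target_mean - w*low)/(1 - w) <= 99
  upper <- (99 - target_mean) / (99 - low[1])
  upper <- min(0.95, max(upper, 1e-6))
  # f can have two roots: a small-w solution whose baseline sits at the 90%
  # demarcation (below-90 mass then comes from the baseline tail) and a
  # larger-w solution whose baseline is clearly above it (mass comes from the
  # hypoxemic dips, the intended structure). Search upward from the minimizer
  # so the dip-driven root is selected.
  w_min <- stats::optimize(f, c(1e-9, upper))$minimum
  if (f(w_min) > 0 || f(upper) < 0) {
    stop_domain(
      "spo2 calibration: (mean = %.2f, fraction = %.3f) unreachable with the configured components",
      target_mean, target_hypox_fraction
    )
  }
  w <- uniroot(f, c(w_min, upper), tol = 1e-10)$root
  list(w = w, base_mean = (target_mean - w * low[1]) / (1 - w))
}

#' Draw a random apnea specification for one session
#'
#' Places `n_events` non-overlapping apnea intervals (with guard bands)
#' uniformly in the session; depths and cycle counts are drawn from the given
#' ranges. Events that cannot be placed without overlap after 200 tries are
#' dropped.
#'
#' @param n_events Number of events to place.
#' @param duration_s Session length, seconds.
#' @param breath_rate Breaths per minute (sets cycle length).
#' @param depth_range,cycles_range Ranges to draw depth (uniform) and cycle
#'   count (integer uniform) from.
#' @param seed RNG seed.
#' @return Data frame `onset_s`, `n_cycles`, `depth` (possibly 0 rows), or
#'   `NULL` when `n_events` is 0.
#' @export
gen_apnea_spec <- function(n_events, duration_s, breath_rate,
                           depth_range = c(0.95, 0.99), cycles_range = c(3L, 5L),
                           seed = 1L) {
  if (n_events == 0) return(NULL)
  period <- 60 / breath_rate
  with_seed(seed, {
    cyc <- sample(cycles_range[1]:cycles_range[2], n_events, replace = TRUE)
    max_dur <- max(cyc) * period
    onset <- numeric(0)
    tries <- 0
    while (length(onset) < n_events && tries < 200) {
      cand <- runif(1, 5, duration_s - max_dur - 5)
      if (!length(onset) || all(abs(cand - onset) > max_dur + 2)) {
        onset <- c(onset, cand)
      }
      tries <- tries + 1
    }
    m <- length(onset)
    if (m == 0) return(NULL)
    o <- order(onset)
    data.frame(onset_s = onset[o], n_cycles = cyc[seq_len(m)][o],
               depth = runif(m, depth_range[1], depth_range[2]))
  })
}

#' Generate a pulse-oximetry stream
#'
#' Emulates collar-sensor acquisition: eight parameters (SaO2, pulse rate,
#' breathing rate, ...) sampled at 5 Hz. SaO2 values come from a two-component
#' Gaussian mixture (baseline vs hypoxemic dips centred below the 90%
#' demarcation) jointly calibrated so the error-free stream attains the target
#' overall mean and the target below-90% fraction; values are capped at 100%.
#' Each sample independently fails at least one non-SaO2 parameter with
#' probability `error_rate` (such samples are excluded downstream). Behaviour
#' labels alternate between rest and active blocks.
#'
#' @param duration_s Stream duration, seconds.
#' @param rate_hz Sampling rate (default 5 Hz).
#' @param target_mean Target mean SaO2 (%) of the error-free stream.
#' @param target_hypox_fraction Target fraction of error-free samples below
#'   90%.
#' @param error_rate Per-sample probability of a parameter failure.
#' @param low Numeric `c(mean, sd)` of the hypoxemic component.
#' @param base_sd SD of the baseline component.
#' @param seed RNG seed.
#' @return Data frame: `t_s`, `sao2_pct`, `ok_1` .. `ok_8` (ok_1 is SaO2
#'   validity), `behavior`.
#' @export
gen_spo2_stream <- function(duration_s, rate_hz = 5, target_mean = 96.48,
                            target_hypox_fraction = 0, error_rate = 0.1,
                            low = c(85, 3), base_sd = 1.2, seed = 1L) {
  stopifnot(duration_s > 0, rate_hz > 0, error_rate >= 0, error_rate <= 1)
  par <- spo2_mixture_params(target_mean, target_hypox_fraction,
                             low = low, base_sd = base_sd)
  n <- floor(duration_s * rate_hz)
  with_seed(seed, {
    from_low <- runif(n) < par$w
    sao2 <- ifelse(from_low,
                   rnorm(n, low[1], low[2]),
                   rnorm(n, par$base_mean, base_sd))
    sao2 <- pmin(sao2, 100)
    ok <- matrix(TRUE, n, 8)
    fails <- runif(n) < error_rate
    if (any(fails)) {
      which_param <- sample(2:8, sum(fails), replace = TRUE)
      ok[cbind(which(fails), which_param)] <- FALSE
    }
    # rest/active occupancy in alternating blocks (~2 min mean dwell)
    behavior <- character(n)
    i <- 1L
    state <- "REST"
    while (i <= n) {
      len <- max(1L, ceiling(rate_hz * stats::rexp(1, 1 / 120)))
      behavior[i:min(n, i + len - 1L)] <- state
      state <- if (state == "REST") "ACTIVE" else "REST"
      i <- i + len
    }
    out <- data.frame(t_s = (seq_len(n) - 1) / rate_hz, sao2_pct = sao2)
    for (j in 1:8) out[[paste0("ok_", j)]] <- ok[, j]
    out$behavior <- behavior
    out
  })
}

# Transition matrix whose stationary distribution is exactly `occupancy`:
# P(i -> j) = a * pi_j off-diagonal, diagonal takes the remainder. `a`
# controls dwell time (smaller a = longer bouts).
state_chain <- function(n_epochs, occupancy, a = 0.15) {
  states <- names(occupancy)
  k <- length(states)
  P <- outer(rep(1, k), occupancy) * a
  diag(P) <- 1 - a * (1 - occupancy)
  if (any(diag(P) < 0)) stop_domain("state chain: dwell parameter too large for these occupancies")
  z <- integer(n_epochs)
  z[1] <- sample.int(k, 1, prob = occupancy)
  for (i in seq_len(n_epochs - 1L)) {
    z[i + 1L] <- sample.int(k, 1, prob = P[z[i], ])
  }
  states[z]
}

# Band-limited Gaussian noise with unit mean periodogram power in the band,
# synthesized in the frequency domain over the whole trace at once.
band_noise <- function(n, fs, f_lo, f_hi) {
  freq <- (0:(n - 1)) * fs / n
  keep <- (freq >= f_lo & freq <= f_hi) | (freq >= fs - f_hi & freq <= fs - f_lo)
  spec <- complex(real = rnorm(n), imaginary = rnorm(n))
  spec[!keep] <- 0
  x <- Re(fft(spec, inverse = TRUE)) / n
  x / sd(x)
}

#' Generate epoch-structured EEG and EMG traces
#'
#' Vigilance states follow a first-order Markov chain over wake, NREM and REM
#' whose stationary occupancy matches the configured targets. Per epoch the
#' EEG is band-limited (0.5-4 Hz, delta) noise whose power is drawn from the
#' state-conditional lognormal, riding on a small broadband floor; the EMG is
#' 10-50 Hz noise with state-conditional power (wake high, NREM intermediate,
#' REM low). Epochs listed in `seizure_epochs` superimpose high-amplitude
#' spike transients on both channels and are flagged in the ground truth.
#'
#' @param duration_s Total duration, a multiple of `epoch_s`.
#' @param occupancy Named fractions `c(wake=, nrem=, rem=)` summing to 1.
#' @param seizure_epochs Integer epoch indices carrying seizure activity.
#' @param sample_rate_hz Sampling rate (2000 Hz matches acquisition; lower
#'   rates give faster tests).
#' @param epoch_s Epoch length, seconds (default 10).
#' @param delta_dist,emg_dist Named lists of `c(meanlog, sdlog)` per state;
#'   defaults from [study_config()].
#' @param seed RNG seed.
#' @return List: `eeg`, `emg` (numeric traces), `sample_rate_hz`, `epoch_s`,
#'   and `ground_truth` data frame (`epoch`, `state`, `seizure`).
#' @export
gen_eeg_emg <- function(duration_s, occupancy = c(wake = 0.45, nrem = 0.45, rem = 0.10),
                        seizure_epochs = integer(0), sample_rate_hz = 2000,
                        epoch_s = 10, delta_dist = NULL, emg_dist = NULL, seed = 1L) {
  if (abs(sum(occupancy) - 1) > 1e-9) stop_domain("gen_eeg_emg: occupancies must sum to 1")
  if (abs(duration_s / epoch_s - round(duration_s / epoch_s)) > 1e-9) {
    stop_domain("gen_eeg_emg: duration must be a multiple of the epoch length")
  }
  cfg <- study_config()
  delta_dist <- delta_dist %||% cfg$sleep$delta
  emg_dist <- emg_dist %||% cfg$sleep$emg
  names(occupancy) <- tolower(names(occupancy))
  n_epochs <- as.integer(round(duration_s / epoch_s))
  n_per <- as.integer(round(epoch_s * sample_rate_hz))
  n <- n_epochs * n_per
  with_seed(seed, {
    states <- state_chain(n_epochs, occupancy[c("wake", "nrem", "rem")])
    delta_pow <- vapply(states, function(s) rlnorm(1, delta_dist[[s]][1], delta_dist[[s]][2]), 0)
    emg_pow <- vapply(states, function(s) rlnorm(1, emg_dist[[s]][1], emg_dist[[s]][2]), 0)
    eeg_carrier <- band_noise(n, sample_rate_hz, 0.5, 4)
    eeg_floor <- band_noise(n, sample_rate_hz, 4, min(40, sample_rate_hz / 2 - 1))
    emg_carrier <- band_noise(n, sample_rate_hz, 10, min(50, sample_rate_hz / 2 - 1))
    scale_eeg <- rep(sqrt(delta_pow), each = n_per)
    scale_emg <- rep(sqrt(emg_pow), each = n_per)
    eeg <- eeg_carrier * scale_eeg + 0.05 * eeg_floor
    emg <- emg_carrier * scale_emg
    seizure <- rep(FALSE, n_epochs)
    if (length(seizure_epochs)) {
      seizure_epochs <- as.integer(seizure_epochs)
      if (any(seizure_epochs < 1 | seizure_epochs > n_epochs)) {
        stop_domain("gen_eeg_emg: seizure epoch index out of range")
      }
      seizure[seizure_epochs] <- TRUE
      for (e in seizure_epochs) {
        idx <- ((e - 1L) * n_per + 1L):(e * n_per)
        spike_at <- seq(1, n_per, by = max(1L, round(sample_rate_hz / 8)))
        spikes <- numeric(n_per)
        spikes[spike_at] <- 25 * sample(c(-1, 1), length(spike_at), replace = TRUE)
        eeg[idx] <- eeg[idx] + spikes
        emg[idx] <- emg[idx] + abs(spikes)
      }
    }
    list(
      eeg = eeg, emg = emg, sample_rate_hz = sample_rate_hz, epoch_s = epoch_s,
      ground_truth = data.frame(
        epoch = seq_len(n_epochs),
        state = toupper(states),
        seizure = seizure
      )
    )
  })
}
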