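#' Duration of two complete respiratory cycles
#'
#' The operational apnea definition requires airflow reduction sustained for
#' at least two complete respiratory cycles; at a baseline rate of f breaths
#' per minute one cycle lasts 60/f seconds, so the window is `2 * 60 / f`.
#'
#' @param breath_rate Baseline eupneic rate, breaths per minute.
#' @return Window length in seconds.
#' @examples
#' two_cycle_window(120) # 1 s
#' @export
two_cycle_window <- function(breath_rate) {
  if (!is.numeric(breath_rate) || any(breath_rate <= 0)) {
    stop_domain("two_cycle_window: breath rate must be positive")
  }
  2 * 60 / breath_rate
}

#' Estimate the eupneic breathing rate from an airflow trace
#'
#' Counts positive-going zero crossings (one per breath) over the leading
#' window of the trace.
#'
#' @param flow Airflow trace.
#' @param sample_rate_hz Sampling rate.
#' @param window_s Leading window used for estimation (default 30 s).
#' @return Breaths per minute.
#' @export
estimate_breath_rate <- function(flow, sample_rate_hz, window_s = 30) {
  n <- min(length(flow), floor(window_s * sample_rate_hz))
  if (n < 2L) stop_domain("estimate_breath_rate: trace too short")
  x <- flow[seq_len(n)]
  up <- sum(x[-1] > 0 & x[-n] <= 0)
  if (up == 0) stop_domain("estimate_breath_rate: no breaths detected in the leading window")
  up / (n / sample_rate_hz) * 60
}

# Sample-level breath-amplitude envelope: running max of |flow| over half a
# respiratory period (|flow| peaks every half period, so this window always
# contains one amplitude extremum while eroding sub-threshold runs by only
# half a cycle), odd window, centered, edges padded.
airflow_envelope <- function(flow, sample_rate_hz, breath_rate) {
  w <- max(3L, as.integer(round(0.5 * 60 / breath_rate * sample_rate_hz)))
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  padded <- c(rep(abs(flow[1]), half), abs(flow), rep(abs(flow[length(flow)]), half))
  zoo::rollmax(zoo::zoo(padded), k = w, align = "center")
}

# Running-median baseline: per-cycle peak amplitudes, baseline of cycle c is
# the median of the preceding `window` cycles (leading cycles use the first
# `window` amplitudes). Returned at sample resolution.
airflow_baseline <- function(flow, sample_rate_hz, breath_rate, window = 10L) {
  period_n <- 60 / breath_rate * sample_rate_hz
  n <- length(flow)
  n_cycles <- max(1L, floor(n / period_n))
  amp <- vapply(seq_len(n_cycles), function(c) {
    lo <- floor((c - 1) * period_n) + 1L
    hi <- min(n, floor(c * period_n))
    max(abs(flow[lo:hi]))
  }, 0)
  base_cycle <- vapply(seq_len(n_cycles), function(c) {
    if (c <= 1L) {
      median(amp[seq_len(min(window, n_cycles))])
    } else {
      median(amp[max(1L, c - window):(c - 1L)])
    }
  }, 0)
  cycle_of <- pmin(n_cycles, floor((seq_len(n) - 1) / period_n) + 1L)
  base_cycle[cycle_of]
}

#' Detect apneas on an airflow trace
#'
#' An apnea is a decrease in airflow of at least 90% sustained for two or
#' more complete respiratory cycles. The detector computes a breath-amplitude
#' envelope (running maximum of |flow| over one respiratory period), a
#' running-median baseline over the preceding `baseline_window` breaths, and
#' emits the maximal contiguous intervals where the envelope is at or below
#' 10% of baseline and the interval spans at least [two_cycle_window()].
#' Events are disjoint and ordered by onset.
#'
#' @param flow Airflow trace (or the list returned by [gen_airflow()]).
#' @param sample_rate_hz Sampling rate (ignored when `flow` is a generator
#'   result).
#' @param breath_rate Baseline breaths/min; estimated from the leading 30 s
#'   of eupnea when `NULL`.
#' @param baseline_window Breaths in the running-median baseline.
#' @return Data frame: `onset_s`, `duration_s`, `depth` (all >= 0.90 by
#'   construction).
#' @export
detect_apneas <- function(flow, sample_rate_hz = NULL, breath_rate = NULL,
                          baseline_window = 10L) {
  if (is.list(flow) && !is.null(flow$flow)) {
    sample_rate_hz <- sample_rate_hz %||% flow$sample_rate_hz
    breath_rate <- breath_rate %||% flow$breath_rate
    flow <- flow$flow
  }
  if (is.null(sample_rate_hz)) stop_domain("detect_apneas: sample_rate_hz required")
  breath_rate <- breath_rate %||% estimate_breath_rate(flow, sample_rate_hz)
  win_s <- two_cycle_window(breath_rate)
  if (length(flow) < 5 * win_s * sample_rate_hz) {
    stop_domain("detect_apneas: trace shorter than five two-cycle windows")
  }
  env <- as.numeric(airflow_envelope(flow, sample_rate_hz, breath_rate))
  base <- airflow_baseline(flow, sample_rate_hz, breath_rate, baseline_window)
  if (any(base <= 0)) stop_domain("detect_apneas: degenerate (zero-amplitude) baseline")
  sub <- env <= 0.10 * base
  r <- rle(sub)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / sample_rate_hz >= win_s)
  out <- data.frame(onset_s = numeric(0), duration_s = numeric(0), depth = numeric(0))
  for (i in which(keep)) {
    idx <- starts[i]:ends[i]
    out <- rbind(out, data.frame(
      onset_s = (starts[i] - 1L) / sample_rate_hz,
      duration_s = r$lengths[i] / sample_rate_hz,
      depth = 1 - min(env[idx] / base[idx])
    ))
  }
  out
}

#' Apnea count for one session
#'
#' @param events Data frame of detected apnea events for one 3-min
#'   collection.
#' @return Integer count >= 0.
#' @export
apnea_count <- function(events) {
  stopifnot(is.data.frame(events))
  nrow(events)
}

#' Apnea susceptibility
#'
#' A subject is susceptible within a PTD bin when any of its sessions in the
#' bin records at least one apneic episode; the cohort-level proportion is
#' the mean of the per-subject indicators.
#'
#' @param counts_by_subject Named list (or list) of integer vectors, one per
#'   subject, of per-session apnea counts in the bin.
#' @return Logical vector, one per subject.
#' @export
susceptibility <- function(counts_by_subject) {
  if (!length(counts_by_subject)) return(logical(0))
  vapply(counts_by_subject, function(x) {
    if (!length(x)) stop_domain("susceptibility: a subject needs at least one session in the bin")
    any(x >= 1)
  }, logical(1))
}
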