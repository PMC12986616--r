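#' Mean heart rate of one ECG segment
#'
#' From a sequence of beat (R-wave) times: rate = 60 * n_intervals /
#' (last - first beat time), i.e. the reciprocal of the mean inter-beat
#' interval expressed in beats per minute.
#'
#' @param beat_times_s Numeric vector of beat times, seconds, increasing.
#' @return Mean heart rate, bpm.
#' @examples
#' segment_mean_hr(seq(0, 10, by = 0.5)) # 120 bpm
#' @export
segment_mean_hr <- function(beat_times_s) {
  if (length(beat_times_s) < 2L) {
    stop_domain("segment_mean_hr: need at least 2 beats")
  }
  if (is.unsorted(beat_times_s, strictly = TRUE)) {
    stop_domain("segment_mean_hr: beat times must be strictly increasing")
  }
  span <- beat_times_s[length(beat_times_s)] - beat_times_s[1]
  60 * (length(beat_times_s) - 1L) / span
}

#' Wild-type heart-rate reference and bradycardia threshold
#'
#' Pools clean segment mean rates from all wild-type subjects (standard- and
#' ketogenic-diet WT rates do not differ, so they are combined), fits the
#' Gaussian reference, and sets the operational bradycardia threshold at the
#' mean minus two standard deviations (with the reported WT distribution of
#' 770 +/- 43 bpm this is 684 bpm). Sample SD (n - 1 denominator) is used.
#'
#' @param wt_segment_means Numeric vector of clean WT segment mean rates
#'   (bpm).
#' @return List of class `wt_reference`: `mean`, `sd`, `threshold`.
#' @examples
#' # any sample with mean 770 and SD 43 gives threshold 684
#' ref <- wt_reference(c(727, 770, 813))
#' @export
wt_reference <- function(wt_segment_means) {
  wt_segment_means <- wt_segment_means[is.finite(wt_segment_means)]
  if (length(wt_segment_means) < 2L) {
    stop_domain("wt_reference: need at least 2 clean WT segments")
  }
  m <- mean(wt_segment_means)
  s <- sd(wt_segment_means)
  structure(list(mean = m, sd = s, threshold = m - 2 * s), class = "wt_reference")
}

#' @export
print.wt_reference <- function(x, ...) {
  cat(sprintf("WT heart-rate reference: %.1f +/- %.1f bpm (mean +/- SD)\n", x$mean, x$sd))
  cat(sprintf("bradycardia threshold (mean - 2 SD): %.1f bpm\n", x$threshold))
  invisible(x)
}

#' Classify an ECG segment as bradycardic
#'
#' A clean segment is bradycardic when its mean heart rate is strictly below
#' the reference threshold (mean - 2 SD of the wild-type distribution).
#' Noisy segments must be excluded before classification.
#'
#' @param mean_hr Segment mean heart rate(s), bpm.
#' @param ref A [wt_reference()].
#' @param noisy Logical flag(s); any `TRUE` is an error (filter first).
#' @return Logical vector.
#' @export
classify_bradycardia <- function(mean_hr, ref, noisy = FALSE) {
  stopifnot(inherits(ref, "wt_reference"))
  if (any(noisy)) {
    stop_domain("classify_bradycardia: noisy segments must be excluded before classification")
  }
  mean_hr < ref$threshold
}

#' Per-subject bradycardic fraction
#'
#' Number of bradycardic clean segments over the number of clean segments;
#' noisy segments are excluded from both numerator and denominator.
#'
#' @param segments Data frame with columns `mean_hr` and `noisy`.
#' @param ref A [wt_reference()].
#' @return Fraction in \[0, 1\].
#' @export
bradycardic_fraction <- function(segments, ref) {
  stopifnot(all(c("mean_hr", "noisy") %in% names(segments)))
  clean <- segments[!segments$noisy, , drop = FALSE]
  if (nrow(clean) == 0L) {
    stop_domain("bradycardic_fraction: no clean segments for this subject")
  }
  mean(classify_bradycardia(clean$mean_hr, ref))
}

# Simple amplitude/variance noise screen for raw segments; a convenience for
# real traces, not used by the synthetic pipeline (noise is a generator flag
# there).
flag_noisy_segments <- function(trace, sample_rate_hz, segment_s = 5,
                                z_cut = 6) {
  n_per <- as.integer(segment_s * sample_rate_hz)
  n_seg <- length(trace) %/% n_per
  vapply(seq_len(n_seg), function(i) {
    x <- trace[((i - 1L) * n_per + 1L):(i * n_per)]
    rng <- diff(range(x))
    any(abs(x - median(x)) > z_cut * (stats::mad(x) + 1e-12)) || rng == 0
  }, logical(1))
}
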