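#' Filter an oximetry stream to error-free measurements
#'
#' A measurement is reliable only when all eight acquired parameters were
#' successfully measured; if SaO2 itself was read but any other parameter
#' failed, the sample is excluded. Order is preserved.
#'
#' @param stream Data frame with logical columns `ok_1` .. `ok_8` (ok_1 =
#'   SaO2 validity).
#' @return The error-free rows of `stream`.
#' @export
filter_error_free <- function(stream) {
  ok_cols <- paste0("ok_", 1:8)
  missing_cols <- setdiff(ok_cols, names(stream))
  if (length(missing_cols)) {
    stop_domain("filter_error_free: missing flags: %s", paste(missing_cols, collapse = ", "))
  }
  if (nrow(stream) == 0L) return(stream)
  keep <- Reduce(`&`, stream[ok_cols])
  stream[keep, , drop = FALSE]
}

#' Session-level oximetry quality control
#'
#' A recording session with fewer than `min_count` error-free measurements is
#' excluded entirely.
#'
#' @param kept_count Number of error-free measurements in the session.
#' @param min_count QC floor (default 50).
#' @return `TRUE` to keep the session, `FALSE` to exclude it.
#' @export
session_qc <- function(kept_count, min_count = 50L) {
  stopifnot(is.numeric(kept_count), kept_count >= 0)
  kept_count >= min_count
}

#' Demarcate hypoxemia
#'
#' An error-free SaO2 reading strictly below 90% saturation is hypoxemic.
#'
#' @param sao2_pct SaO2 values, percent.
#' @return Logical vector.
#' @export
flag_hypoxemia <- function(sao2_pct) {
  sao2_pct < 90
}

#' Per-subject hypoxemia fraction
#'
#' Hypoxemic measurements over error-free measurements, pooled across the
#' subject's QC-passing sessions (sessions failing [session_qc()] contribute
#' nothing).
#'
#' @param sessions List of oximetry streams (data frames with `sao2_pct` and
#'   `ok_1` .. `ok_8`) for one subject.
#' @param min_count Session QC floor.
#' @return Fraction in \[0, 1\].
#' @export
hypoxemia_fraction <- function(sessions, min_count = 50L) {
  if (is.data.frame(sessions)) sessions <- list(sessions)
  n_hypox <- 0L
  n_free <- 0L
  for (s in sessions) {
    kept <- filter_error_free(s)
    if (!session_qc(nrow(kept), min_count)) next
    n_free <- n_free + nrow(kept)
    n_hypox <- n_hypox + sum(flag_hypoxemia(kept$sao2_pct))
  }
  if (n_free == 0L) {
    stop_domain("hypoxemia_fraction: no QC-passing sessions for this subject")
  }
  n_hypox / n_free
}

#' Pooled mean SaO2 over QC-passing sessions
#'
#' @inheritParams hypoxemia_fraction
#' @return Mean SaO2 (%) over the subject's error-free measurements.
#' @export
mean_sao2 <- function(sessions, min_count = 50L) {
  if (is.data.frame(sessions)) sessions <- list(sessions)
  total <- 0
  n_free <- 0L
  for (s in sessions) {
    kept <- filter_error_free(s)
    if (!session_qc(nrow(kept), min_count)) next
    total <- total + sum(kept$sao2_pct)
    n_free <- n_free + nrow(kept)
  }
  if (n_free == 0L) stop_domain("mean_sao2: no QC-passing sessions for this subject")
  total / n_free
}
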