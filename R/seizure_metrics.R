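validate_seizure_events <- function(events, session_duration_s = NULL) {
  required <- c("onset_s", "duration_s", "severity")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols)) {
    stop_domain("seizure events: missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  if (nrow(events) == 0L) return(invisible(events))
  if ("session" %in% names(events) && length(unique(events$session)) > 1L) {
    stop_domain("seizure events: rows span multiple sessions; score one session at a time")
  }
  if (any(events$severity < 1 | events$severity > 6 | events$severity != floor(events$severity))) {
    stop_domain("seizure events: severity must be an integer grade 1-6 (modified Racine scale)")
  }
  if (any(events$duration_s <= 0)) stop_domain("seizure events: duration must be positive")
  if (!is.null(session_duration_s) &&
      any(events$onset_s + events$duration_s > session_duration_s + 1e-9)) {
    stop_domain("seizure events: event extends past the end of the session")
  }
  invisible(events)
}

#' Seizure count for one recording session
#'
#' All annotated events in the 48 h session are counted; no filtering is
#' applied.
#'
#' @param events Data frame of seizure events for one session with columns
#'   `onset_s`, `duration_s`, `severity` (integer 1-6, modified Racine).
#' @param session_duration_s Optional session length used to validate onsets.
#' @return Integer count >= 0.
#' @export
seizure_count <- function(events, session_duration_s = NULL) {
  validate_seizure_events(events, session_duration_s)
  nrow(events)
}

#' Seizure burden for one recording session
#'
#' Burden is the sum over events of severity times duration
#' (units: severity-seconds): for each seizure the Racine grade and the
#' duration are multiplied, and the products summed over the session. Zero
#' for a session with no seizures; additive over disjoint subsets of events.
#'
#' @inheritParams seizure_count
#' @return Numeric burden (severity * seconds).
#' @examples
#' ev <- data.frame(onset_s = c(100, 2000), duration_s = c(30, 45), severity = c(2L, 6L))
#' seizure_burden(ev) # 2*30 + 6*45 = 330
#' @export
seizure_burden <- function(events, session_duration_s = NULL) {
  validate_seizure_events(events, session_duration_s)
  if (nrow(events) == 0L) return(0)
  sum(events$severity * events$duration_s)
}
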