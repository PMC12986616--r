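#' Write and read columnar signal containers
#'
#' Waveforms are stored as plain CSV (one column per channel) with a JSON
#' sidecar describing channels, sampling rate and units, so a session
#' round-trips without loss of metadata.
#'
#' @param signals Named list or data frame of equal-length numeric channels.
#' @param path CSV path; the sidecar is written at `<path>.json`.
#' @param sample_rate_hz Sampling rate common to all channels.
#' @param units Named character vector of per-channel units (recycled).
#' @return `write_signal` returns `path` invisibly; `read_signal` a list with
#'   `data` (data frame) and `meta`.
#' @export
write_signal <- function(signals, path, sample_rate_hz, units = "a.u.") {
  df <- as.data.frame(signals)
  if (!nrow(df)) stop_domain("write_signal: empty signal")
  meta <- list(
    channels = names(df),
    sample_rate_hz = sample_rate_hz,
    units = as.list(setNames(rep_len(units, ncol(df)), names(df))),
    n_samples = nrow(df)
  )
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  data <- read.csv(path)
  if (nrow(data) != meta$n_samples) {
    stop_domain("read_signal: %s has %d samples, sidecar says %d",
                path, nrow(data), meta$n_samples)
  }
  list(data = data, meta = meta)
}
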