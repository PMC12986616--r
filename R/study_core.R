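#' Days prior to death (PTD) for a recording session
#'
#' Retrospective realignment: every endpoint is re-indexed by the number of
#' days between the recording session and the subject's day of sudden death.
#' A session the day before death is at 1 day PTD; the day of death itself is
#' PTD 0 and never carries a session, so `death_day` must exceed `record_day`.
#'
#' @param record_day Postnatal day of the recording session (integer).
#' @param death_day Postnatal day of sudden death (integer).
#' @param subject_id Optional label used in error messages.
#' @return Integer days prior to death, `death_day - record_day` (>= 1).
#' @examples
#' compute_ptd(56, 57) # session the day before death -> 1
#' compute_ptd(30, 65) # -> 35
#' @export
compute_ptd <- function(record_day, death_day, subject_id = NULL) {
  stopifnot(is.numeric(record_day), is.numeric(death_day))
  if (any(record_day > death_day)) {
    bad <- which(record_day > death_day)[1]
    stop_domain(
      "alignment error%s: record_day (%s) is after death_day (%s)",
      if (is.null(subject_id)) "" else paste0(" for subject ", subject_id),
      record_day[bad], death_day[bad]
    )
  }
  if (any(record_day == death_day)) {
    stop_domain(
      "alignment error%s: a session on the death day itself (day %s) cannot be plotted retrospectively",
      if (is.null(subject_id)) "" else paste0(" for subject ", subject_id),
      death_day[which(record_day == death_day)[1]]
    )
  }
  as.integer(death_day - record_day)
}

#' Pool days-prior-to-death into 10-day bins
#'
#' Bin 1 covers 1-10 days PTD, bin 2 covers 11-20, and so on: bins are the
#' closed integer ranges `[10(k-1)+1, 10k]`, i.e. `bin = ceiling(ptd / 10)`.
#'
#' @param ptd Positive integer days prior to death (vectorised).
#' @return Integer bin index (1-based).
#' @examples
#' bin_ptd(c(1, 10, 11, 35)) # 1 1 2 4
#' @export
bin_ptd <- function(ptd) {
  stopifnot(is.numeric(ptd))
  if (any(ptd <= 0) || any(ptd != floor(ptd))) {
    stop_domain("ptd must be a positive integer (day of death is PTD 0 and carries no session)")
  }
  as.integer(ceiling(ptd / 10))
}

#' Pool endpoint frames by cohort and PTD bin
#'
#' Partitions per-session endpoint values into (genotype, diet, bin) groups.
#' Every input row lands in exactly one group; nothing is lost or duplicated.
#'
#' @param frames Data frame with columns `subject_id`, `genotype`, `diet`,
#'   `ptd`, `value`, `endpoint_name`.
#' @return The input with a `bin_index` column and a `group` factor keyed
#'   `genotype.diet.bin`.
#' @export
pool_by_bin <- function(frames) {
  required <- c("subject_id", "genotype", "diet", "ptd", "value", "endpoint_name")
  missing_cols <- setdiff(required, names(frames))
  if (length(missing_cols)) {
    stop_domain("pool_by_bin: missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  if (nrow(frames) == 0L) {
    out <- frames
    out$bin_index <- integer(0)
    out$group <- character(0)
    return(out)
  }
  if (length(unique(frames$endpoint_name)) > 1L) {
    stop_domain(
      "pool_by_bin: frames mix endpoints (%s); pool one endpoint at a time",
      paste(unique(frames$endpoint_name), collapse = ", ")
    )
  }
  frames$bin_index <- bin_ptd(frames$ptd)
  frames$group <- interaction(frames$genotype, frames$diet, frames$bin_index, drop = TRUE)
  frames
}

#' Validate a study manifest
#'
#' A manifest describes one subject per row: genotype (WT/KO), diet (SD/KD),
#' sex, postnatal day of death, and optional paired littermate. All KO
#' subjects die (100% mortality in this model), so `death_day` is required for
#' KO rows and must exceed weaning (day 21); a paired WT littermate is
#' euthanized on the same day as its KO partner, so its `death_day` must match.
#'
#' @param manifest Data frame with columns `subject_id`, `genotype`, `diet`,
#'   `sex`, `death_day`, and optionally `paired_littermate`.
#' @return The manifest, invisibly, after validation.
#' @export
validate_manifest <- function(manifest) {
  required <- c("subject_id", "genotype", "diet", "sex", "death_day")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols)) {
    stop_domain("manifest: missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(manifest$subject_id)) {
    stop_domain("manifest: duplicated subject_id")
  }
  if (!all(manifest$genotype %in% c("WT", "KO"))) stop_domain("manifest: genotype must be WT or KO")
  if (!all(manifest$diet %in% c("SD", "KD"))) stop_domain("manifest: diet must be SD or KD")
  ko <- manifest$genotype == "KO"
  if (any(ko & is.na(manifest$death_day))) {
    stop_domain("manifest: death_day is required for KO subjects (100%% mortality)")
  }
  known <- !is.na(manifest$death_day)
  if (any(known & manifest$death_day <= 21)) {
    stop_domain("manifest: death_day must be after weaning (day 21)")
  }
  if ("paired_littermate" %in% names(manifest)) {
    paired <- which(!is.na(manifest$paired_littermate) & nzchar(manifest$paired_littermate))
    for (i in paired) {
      j <- match(manifest$paired_littermate[i], manifest$subject_id)
      if (is.na(j)) next
      if (manifest$genotype[i] == "WT" && manifest$genotype[j] == "KO" &&
          !is.na(manifest$death_day[i]) && manifest$death_day[i] != manifest$death_day[j]) {
        stop_domain(
          "manifest: WT littermate %s must share death_day with paired KO %s",
          manifest$subject_id[i], manifest$subject_id[j]
        )
      }
    }
  }
  invisible(manifest)
}

#' Validate a sessions table against a manifest
#'
#' Sessions are one recording of one modality on one postnatal day. Recordings
#' are scheduled roughly every 10 days; for each subject and modality the
#' record days must be strictly increasing and must not fall after death.
#'
#' @param sessions Data frame with columns `subject_id`, `modality`,
#'   `record_day`, `duration_s`.
#' @param manifest A validated study manifest.
#' @return The sessions table, invisibly.
#' @export
validate_sessions <- function(sessions, manifest) {
  required <- c("subject_id", "modality", "record_day", "duration_s")
  missing_cols <- setdiff(required, names(sessions))
  if (length(missing_cols)) {
    stop_domain("sessions: missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  mods <- c("EEG_EMG", "ECG", "AIRWAY", "OXIMETRY")
  if (!all(sessions$modality %in% mods)) {
    stop_domain("sessions: modality must be one of %s", paste(mods, collapse = ", "))
  }
  unknown <- setdiff(sessions$subject_id, manifest$subject_id)
  if (length(unknown)) {
    stop_domain("sessions: unknown subject_id: %s", paste(unknown, collapse = ", "))
  }
  dd <- manifest$death_day[match(sessions$subject_id, manifest$subject_id)]
  late <- !is.na(dd) & sessions$record_day > dd
  if (any(late)) {
    stop_domain(
      "sessions: record_day after death_day for subject %s",
      sessions$subject_id[which(late)[1]]
    )
  }
  by_key <- split(sessions$record_day, paste(sessions$subject_id, sessions$modality))
  for (k in names(by_key)) {
    if (is.unsorted(by_key[[k]], strictly = TRUE)) {
      stop_domain("sessions: record_day not strictly increasing for %s", k)
    }
  }
  invisible(sessions)
}

#' Read and write study manifests
#'
#' CSV and JSON representations round-trip bit-identically (column order and
#' types preserved).
#'
#' @param manifest Manifest data frame.
#' @param path File path; format chosen by extension (`.csv` or `.json`).
#' @return `write_manifest` returns `path` invisibly; `read_manifest` the
#'   validated manifest.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(manifest, path, dataframe = "rows", na = "null", digits = NA)
  } else {
    write.csv(manifest, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  }
  validate_manifest(m)
  m
}
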