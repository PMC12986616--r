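# Pick the target for a PTD bin from a named per-bin vector/list, reusing the
# deepest configured bin for earlier (larger-index) bins.
bin_target <- function(per_bin, bin) {
  keys <- as.integer(names(per_bin))
  key <- as.character(max(min(bin, max(keys)), min(keys)))
  per_bin[[key]]
}

cohort_of <- function(genotype, diet) paste(genotype, diet, sep = "_")

schedule_sessions <- function(death_day, first_day = 35) {
  days <- seq(death_day - 1, first_day, by = -10)
  sort(days[days >= first_day])
}

#' Simulate a complete synthetic study to disk
#'
#' Generates the study manifest (KO cohorts with paired wild-type
#' littermates euthanized on the KO's death day), survival records, session
#' schedules (~every 10 days from postnatal day 35 until death), seizure
#' annotations, ECG segment tables, airflow traces with injected apneas,
#' and pulse-oximetry streams, all calibrated to the configured cohort-level
#' targets. EEG/EMG waveforms are written for the final session of the sleep
#' subcohort (the first six KO per diet and their littermates).
#'
#' @param config A [study_config()].
#' @param seed Study seed; expanded into per-modality substreams.
#' @param outdir Output directory (created if needed).
#' @param modalities Subset of `c("eeg", "ecg", "airway", "spo2")`.
#' @return The run manifest (invisibly), also written as
#'   `run_manifest.json`.
#' @export
run_simulate <- function(config = study_config(), seed = 1L, outdir,
                         modalities = c("eeg", "ecg", "airway", "spo2")) {
  stopifnot(inherits(config, "study_config"))
  modalities <- match.arg(modalities, several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  # --- subjects and survival -------------------------------------------------
  surv_seed <- substream_seed(seed, "survival")
  manifest <- do.call(rbind, lapply(names(config$survival), function(co) {
    s <- config$survival[[co]]
    diet <- sub("^KO_", "", co)
    times <- gen_survival(s$n, s$mean, s$sem, seed = substream_seed(surv_seed, co))
    ko_ids <- sprintf("KO-%s-%02d", diet, seq_len(s$n))
    wt_ids <- sprintf("WT-%s-%02d", diet, seq_len(s$n))
    rbind(
      data.frame(subject_id = ko_ids, genotype = "KO", diet = diet,
                 sex = rep_len(c("M", "F"), s$n), death_day = times,
                 paired_littermate = wt_ids),
      data.frame(subject_id = wt_ids, genotype = "WT", diet = diet,
                 sex = rep_len(c("F", "M"), s$n), death_day = times,
                 paired_littermate = ko_ids)
    )
  }))
  validate_manifest(manifest)
  write_manifest(manifest, file.path(outdir, "manifest.csv"))
  surv <- manifest[manifest$genotype == "KO",
                   c("subject_id", "genotype", "diet", "death_day")]
  surv_out <- data.frame(subject_id = surv$subject_id,
                         cohort = cohort_of(surv$genotype, surv$diet),
                         time_days = surv$death_day, event = TRUE)
  write.csv(surv_out, file.path(outdir, "survival.csv"), row.names = FALSE)

  threshold <- config$wt_hr$mean - 2 * config$wt_hr$sd
  sessions <- list()
  counts <- list(subjects = nrow(manifest))

  # sleep/seizure subcohort: first six KO per diet plus their littermates
  sleep_ids <- unlist(lapply(c("SD", "KD"), function(diet) {
    ko <- manifest$subject_id[manifest$genotype == "KO" & manifest$diet == diet]
    ko <- head(ko, 6)
    wt <- manifest$paired_littermate[match(ko, manifest$subject_id)]
    c(ko, wt)
  }))

  seizure_rows <- list()
  ecg_rows <- list()
  if ("airway" %in% modalities) dir.create(file.path(outdir, "airway"), showWarnings = FALSE)
  if ("spo2" %in% modalities) dir.create(file.path(outdir, "spo2"), showWarnings = FALSE)
  if ("eeg" %in% modalities) dir.create(file.path(outdir, "eeg"), showWarnings = FALSE)

  for (i in seq_len(nrow(manifest))) {
    sub <- manifest[i, ]
    co <- cohort_of(sub$genotype, sub$diet)
    days <- schedule_sessions(sub$death_day)
    if (!length(days)) next
    bins <- bin_ptd(compute_ptd(days, sub$death_day))

    if ("ecg" %in% modalities) {
      for (k in seq_along(days)) {
        target <- bin_target(config$brady_fraction[[co]], bins[k])
        w <- calibrate_mixture_weight(
          target, threshold,
          low = c(config$hr_low$mean, config$hr_low$sd),
          high = c(config$wt_hr$mean, config$wt_hr$sd)
        )
        seg <- gen_ecg_segments(
          n_segments = config$segments_per_session, mixture_weight = w,
          high = c(config$wt_hr$mean, config$wt_hr$sd),
          low = c(config$hr_low$mean, config$hr_low$sd),
          noise_fraction = config$segment_noise_fraction,
          seed = substream_seed(seed, paste0("ecg/", sub$subject_id, "/", days[k]))
        )
        seg <- data.frame(subject_id = sub$subject_id, record_day = days[k],
                          n_beats = seg$n_beats, mean_hr_bpm = seg$mean_hr,
                          noisy = seg$noisy)
        ecg_rows[[length(ecg_rows) + 1L]] <- seg
        sessions[[length(sessions) + 1L]] <- data.frame(
          subject_id = sub$subject_id, modality = "ECG", record_day = days[k],
          duration_s = 300, payload_path = ""
        )
      }
    }

    if ("airway" %in% modalities) {
      for (k in seq_along(days)) {
        rate <- bin_target(config$apnea_rate[[co]], bins[k])
        sseed <- substream_seed(seed, paste0("airway/", sub$subject_id, "/", days[k]))
        n_ev <- with_seed(sseed, rpois(1, rate))
        spec <- gen_apnea_spec(n_ev, config$airflow_session_s,
                               config$breath_rate, seed = sseed + 7L)
        tr <- gen_airflow(config$airflow_session_s, config$breath_rate,
                          apnea_spec = spec,
                          sample_rate_hz = config$airflow_rate_hz,
                          seed = sseed + 1L)
        rel <- file.path("airway", sprintf("%s_d%03d.csv", sub$subject_id, days[k]))
        write_signal(list(flow = tr$flow), file.path(outdir, rel),
                     sample_rate_hz = config$airflow_rate_hz, units = "mL/s")
        write.csv(tr$ground_truth,
                  file.path(outdir, sub("\\.csv$", "_truth.csv", rel)),
                  row.names = FALSE)
        sessions[[length(sessions) + 1L]] <- data.frame(
          subject_id = sub$subject_id, modality = "AIRWAY", record_day = days[k],
          duration_s = config$airflow_session_s, payload_path = rel
        )
      }
    }

    if ("spo2" %in% modalities) {
      targets <- if (sub$genotype == "WT") config$spo2$targets$WT else config$spo2$targets[[co]]
      for (k in seq_along(days)) {
        tgt <- bin_target(targets, bins[k])
        st <- gen_spo2_stream(
          duration_s = config$spo2$session_s, rate_hz = config$spo2$rate_hz,
          target_mean = tgt[1], target_hypox_fraction = tgt[2],
          error_rate = config$spo2$error_rate,
          low = c(config$spo2$low$mean, config$spo2$low$sd),
          base_sd = config$spo2$base_sd,
          seed = substream_seed(seed, paste0("spo2/", sub$subject_id, "/", days[k]))
        )
        rel <- file.path("spo2", sprintf("%s_d%03d.csv", sub$subject_id, days[k]))
        write.csv(st, file.path(outdir, rel), row.names = FALSE)
        sessions[[length(sessions) + 1L]] <- data.frame(
          subject_id = sub$subject_id, modality = "OXIMETRY", record_day = days[k],
          duration_s = config$spo2$session_s, payload_path = rel
        )
      }
    }

    if ("eeg" %in% modalities && sub$subject_id %in% sleep_ids) {
      seiz_rate <- config$seizure$rate[[co]]
      for (k in seq_along(days)) {
        sseed <- substream_seed(seed, paste0("seiz/", sub$subject_id, "/", days[k]))
        ev <- with_seed(sseed, {
          n_ev <- rpois(1, seiz_rate)
          if (n_ev == 0) NULL else data.frame(
            subject_id = sub$subject_id, record_day = days[k],
            onset_s = sort(runif(n_ev, 0, 48 * 3600 - 300)),
            duration_s = rlnorm(n_ev, config$seizure$duration_meanlog,
                                config$seizure$duration_sdlog),
            severity = sample(1:6, n_ev, replace = TRUE,
                              prob = config$seizure$severity_probs)
          )
        })
        if (!is.null(ev)) seizure_rows[[length(seizure_rows) + 1L]] <- ev
        is_final <- k == length(days)
        rel <- ""
        if (is_final) {
          # sleep staging uses the final recording before death (sleep-phase
          # window only)
          occ <- if (sub$genotype == "KO") c(wake = 0.70, nrem = 0.25, rem = 0.05)
                 else config$sleep$occupancy
          ee <- gen_eeg_emg(
            duration_s = config$sleep$window_s, occupancy = occ,
            sample_rate_hz = config$eeg_rate_hz,
            epoch_s = config$sleep$epoch_s,
            delta_dist = config$sleep$delta, emg_dist = config$sleep$emg,
            seed = substream_seed(seed, paste0("eeg/", sub$subject_id))
          )
          rel <- file.path("eeg", sprintf("%s_d%03d.csv", sub$subject_id, days[k]))
          write_signal(list(eeg = ee$eeg, emg = ee$emg), file.path(outdir, rel),
                       sample_rate_hz = config$eeg_rate_hz, units = "uV")
          write.csv(ee$ground_truth,
                    file.path(outdir, sub("\\.csv$", "_truth.csv", rel)),
                    row.names = FALSE)
        }
        sessions[[length(sessions) + 1L]] <- data.frame(
          subject_id = sub$subject_id, modality = "EEG_EMG", record_day = days[k],
          duration_s = 48 * 3600, payload_path = rel
        )
      }
    }
  }

  sessions <- do.call(rbind, sessions)
  sessions <- sessions[order(sessions$subject_id, sessions$modality, sessions$record_day), ]
  validate_sessions(sessions, manifest)
  write.csv(sessions, file.path(outdir, "sessions.csv"), row.names = FALSE)
  if (length(seizure_rows)) {
    write.csv(do.call(rbind, seizure_rows), file.path(outdir, "seizures.csv"),
              row.names = FALSE)
  } else if ("eeg" %in% modalities) {
    write.csv(data.frame(subject_id = character(0), record_day = integer(0),
                         onset_s = numeric(0), duration_s = numeric(0),
                         severity = integer(0)),
              file.path(outdir, "seizures.csv"), row.names = FALSE)
  }
  if (length(ecg_rows)) {
    write.csv(do.call(rbind, ecg_rows), file.path(outdir, "ecg_segments.csv"),
              row.names = FALSE)
  }

  counts$sessions <- nrow(sessions)
  counts$seizures <- if (length(seizure_rows)) sum(vapply(seizure_rows, nrow, 0L)) else 0L
  run_manifest <- list(seed = seed, modalities = modalities, counts = counts,
                       config = unclass(config))
  jsonlite::write_json(run_manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  message(sprintf("simulated %d subjects, %d sessions, %d seizures -> %s",
                  counts$subjects, counts$sessions, counts$seizures, outdir))
  invisible(run_manifest)
}

#' Analyze a simulated (or equivalently structured) study
#'
#' Runs every endpoint pipeline over a study directory written by
#' [run_simulate()]: survival (Kaplan-Meier, log-rank, hazard ratio),
#' seizure count and burden, bradycardic fractions against the pooled
#' wild-type reference, apnea counts and susceptibility, and oximetry
#' mean SaO2/hypoxemia fractions. Endpoints are produced both prospectively
#' (by postnatal day) and retrospectively (by days-prior-to-death bin).
#' Missing modality directories yield a warning and partial results.
#'
#' @param study_dir Directory written by [run_simulate()].
#' @param outdir Results directory (default `<study_dir>/results`).
#' @return List of endpoint tables and statistics (also written as CSV/JSON).
#' @export
run_analyze <- function(study_dir, outdir = file.path(study_dir, "results")) {
  manifest <- read_manifest(file.path(study_dir, "manifest.csv"))
  sessions <- read.csv(file.path(study_dir, "sessions.csv"))
  validate_sessions(sessions, manifest)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  death_of <- setNames(manifest$death_day, manifest$subject_id)
  cohort_lookup <- setNames(cohort_of(manifest$genotype, manifest$diet),
                            manifest$subject_id)
  add_ptd <- function(df) {
    df$ptd <- compute_ptd(df$record_day, death_of[df$subject_id])
    df$bin_index <- bin_ptd(df$ptd)
    df$cohort <- cohort_lookup[df$subject_id]
    df
  }

  # --- survival --------------------------------------------------------------
  surv_path <- file.path(study_dir, "survival.csv")
  if (file.exists(surv_path)) {
    surv <- read.csv(surv_path)
    by_cohort <- split(surv, surv$cohort)
    res$survival <- list(
      cohorts = lapply(by_cohort, function(g) {
        km <- km_curve(data.frame(time = g$time_days, event = g$event))
        list(n = km$n, mean = km$mean, median = km$median)
      })
    )
    if (all(c("KO_SD", "KO_KD") %in% names(by_cohort))) {
      a <- data.frame(time = by_cohort$KO_SD$time_days, event = by_cohort$KO_SD$event)
      b <- data.frame(time = by_cohort$KO_KD$time_days, event = by_cohort$KO_KD$event)
      res$survival$logrank <- logrank_test(a, b)
      res$survival$hazard_ratio <- tryCatch(hazard_ratio_mh(a, b), error = function(e) NULL)
    }
  } else {
    warning("no survival.csv; skipping survival analysis")
  }

  # --- seizures --------------------------------------------------------------
  seiz_path <- file.path(study_dir, "seizures.csv")
  if (file.exists(seiz_path)) {
    seiz <- read.csv(seiz_path)
    eeg_sessions <- sessions[sessions$modality == "EEG_EMG", ]
    per_session <- do.call(rbind, lapply(seq_len(nrow(eeg_sessions)), function(i) {
      s <- eeg_sessions[i, ]
      ev <- seiz[seiz$subject_id == s$subject_id & seiz$record_day == s$record_day, ]
      data.frame(subject_id = s$subject_id, record_day = s$record_day,
                 seizure_count = seizure_count(ev, s$duration_s),
                 seizure_burden = seizure_burden(ev, s$duration_s))
    }))
    if (!is.null(per_session) && nrow(per_session)) {
      per_session <- add_ptd(per_session)
      write.csv(per_session, file.path(outdir, "seizure_endpoints.csv"),
                row.names = FALSE)
      res$seizures <- per_session
    }
  }

  # --- ECG / bradycardia -----------------------------------------------------
  ecg_path <- file.path(study_dir, "ecg_segments.csv")
  if (file.exists(ecg_path)) {
    seg <- read.csv(ecg_path)
    seg$cohort <- cohort_lookup[seg$subject_id]
    wt_clean <- seg[grepl("^WT", seg$cohort) & !seg$noisy, ]
    ref <- wt_reference(wt_clean$mean_hr_bpm)
    seg <- add_ptd(seg)
    key <- interaction(seg$subject_id, seg$bin_index, drop = TRUE)
    brady <- do.call(rbind, lapply(split(seg, key), function(g) {
      clean <- g[!g$noisy, ]
      if (!nrow(clean)) return(NULL)
      data.frame(subject_id = g$subject_id[1], cohort = g$cohort[1],
                 bin_index = g$bin_index[1], n_segments = nrow(clean),
                 bradycardic_fraction =
                   bradycardic_fraction(data.frame(mean_hr = clean$mean_hr_bpm,
                                                   noisy = clean$noisy), ref))
    }))
    rownames(brady) <- NULL
    write.csv(brady, file.path(outdir, "bradycardia_endpoints.csv"), row.names = FALSE)
    jsonlite::write_json(unclass(ref), file.path(outdir, "wt_reference.json"),
                         auto_unbox = TRUE, digits = NA)
    res$wt_reference <- ref
    res$bradycardia <- brady
    bin1 <- brady[brady$bin_index == 1, ]
    bin1$genotype <- sub("_.*", "", bin1$cohort)
    bin1$diet <- sub(".*_", "", bin1$cohort)
    res$stats$bradycardia_anova <- tryCatch(
      two_way_anova(data.frame(value = bin1$bradycardic_fraction,
                               factor_a = bin1$genotype, factor_b = bin1$diet)),
      error = function(e) NULL
    )
  }

  # --- airflow / apnea -------------------------------------------------------
  air_sessions <- sessions[sessions$modality == "AIRWAY" & nzchar(sessions$payload_path), ]
  if (nrow(air_sessions)) {
    missing_files <- !file.exists(file.path(study_dir, air_sessions$payload_path))
    if (any(missing_files)) {
      warning(sprintf("%d airway payloads missing; partial apnea results",
                      sum(missing_files)))
      air_sessions <- air_sessions[!missing_files, ]
    }
  }
  if (nrow(air_sessions)) {
    apnea <- do.call(rbind, lapply(seq_len(nrow(air_sessions)), function(i) {
      s <- air_sessions[i, ]
      sig <- read_signal(file.path(study_dir, s$payload_path))
      ev <- detect_apneas(sig$data$flow, sample_rate_hz = sig$meta$sample_rate_hz)
      data.frame(subject_id = s$subject_id, record_day = s$record_day,
                 apnea_count = apnea_count(ev))
    }))
    apnea <- add_ptd(apnea)
    write.csv(apnea, file.path(outdir, "apnea_endpoints.csv"), row.names = FALSE)
    res$apnea <- apnea
    # susceptibility per (cohort, bin): any session with >= 1 episode
    key <- interaction(apnea$cohort, apnea$bin_index, drop = TRUE)
    susc <- do.call(rbind, lapply(split(apnea, key), function(g) {
      by_subj <- split(g$apnea_count, g$subject_id)
      sus <- susceptibility(by_subj)
      data.frame(cohort = g$cohort[1], bin_index = g$bin_index[1],
                 n_subjects = length(sus), n_susceptible = sum(sus),
                 proportion = mean(sus))
    }))
    rownames(susc) <- NULL
    write.csv(susc, file.path(outdir, "apnea_susceptibility.csv"), row.names = FALSE)
    res$apnea_susceptibility <- susc
  } else if (!dir.exists(file.path(study_dir, "airway"))) {
    warning("no airway data; skipping apnea analysis")
  }

  # --- oximetry --------------------------------------------------------------
  ox_sessions <- sessions[sessions$modality == "OXIMETRY", ]
  if (nrow(ox_sessions)) {
    ox_sessions <- add_ptd(ox_sessions)
    key <- interaction(ox_sessions$subject_id, ox_sessions$bin_index, drop = TRUE)
    ox <- do.call(rbind, lapply(split(ox_sessions, key), function(g) {
      streams <- lapply(file.path(study_dir, g$payload_path), read.csv)
      ok <- tryCatch(list(
        mean_sao2 = mean_sao2(streams),
        hypox = hypoxemia_fraction(streams)
      ), error = function(e) NULL)
      if (is.null(ok)) return(NULL)
      data.frame(subject_id = g$subject_id[1], cohort = g$cohort[1],
                 bin_index = g$bin_index[1], n_sessions = nrow(g),
                 mean_sao2 = ok$mean_sao2, hypoxemia_fraction = ok$hypox)
    }))
    rownames(ox) <- NULL
    write.csv(ox, file.path(outdir, "oximetry_endpoints.csv"), row.names = FALSE)
    res$oximetry <- ox
  } else if (!dir.exists(file.path(study_dir, "spo2"))) {
    warning("no oximetry data; skipping oximetry analysis")
  }

  # --- EEG / sleep staging ---------------------------------------------------
  eeg_sessions <- sessions[sessions$modality == "EEG_EMG" & nzchar(sessions$payload_path), ]
  if (nrow(eeg_sessions)) {
    occ_rows <- do.call(rbind, lapply(seq_len(nrow(eeg_sessions)), function(i) {
      s <- eeg_sessions[i, ]
      sig <- read_signal(file.path(study_dir, s$payload_path))
      feats <- epoch_features(sig$data$eeg, sig$data$emg, sig$meta$sample_rate_hz)
      states <- classify_states(feats, seed = 1L)
      occ <- occupancy(states)
      hyp <- data.frame(epoch = feats$epoch, state = states)
      write.csv(hyp, file.path(outdir, sprintf("hypnogram_%s.csv", s$subject_id)),
                row.names = FALSE)
      data.frame(subject_id = s$subject_id, record_day = s$record_day,
                 wake = occ["wake"], nrem = occ["nrem"], rem = occ["rem"])
    }))
    rownames(occ_rows) <- NULL
    occ_rows <- add_ptd(occ_rows)
    write.csv(occ_rows, file.path(outdir, "sleep_endpoints.csv"), row.names = FALSE)
    res$sleep <- occ_rows
  }

  stats_out <- res[c("survival", "stats")]
  jsonlite::write_json(stats_out, file.path(outdir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(res)
}

#' Summarize analysis results as cohort tables
#'
#' Renders per-(cohort, PTD-bin) summary tables (n, mean, SEM) for each
#' endpoint CSV produced by [run_analyze()]. No statistics are computed
#' here; row order is deterministic.
#'
#' @param results_dir Directory written by [run_analyze()].
#' @param outdir Where to write `summary_*.csv` (default `results_dir`).
#' @return Named list of summary data frames, invisibly.
#' @export
run_report <- function(results_dir, outdir = results_dir) {
  endpoints <- list(
    seizure = c("seizure_endpoints.csv", "seizure_count", "seizure_burden"),
    bradycardia = c("bradycardia_endpoints.csv", "bradycardic_fraction"),
    apnea = c("apnea_endpoints.csv", "apnea_count"),
    oximetry = c("oximetry_endpoints.csv", "mean_sao2", "hypoxemia_fraction"),
    sleep = c("sleep_endpoints.csv", "wake", "nrem", "rem")
  )
  found <- FALSE
  out <- list()
  for (nm in names(endpoints)) {
    path <- file.path(results_dir, endpoints[[nm]][1])
    if (!file.exists(path)) next
    found <- TRUE
    df <- read.csv(path)
    value_cols <- intersect(endpoints[[nm]][-1], names(df))
    key <- interaction(df$cohort, df$bin_index, drop = TRUE)
    summ <- do.call(rbind, lapply(split(df, key), function(g) {
      row <- data.frame(cohort = g$cohort[1], bin_index = g$bin_index[1],
                        n = nrow(g))
      for (v in value_cols) {
        row[[paste0(v, "_mean")]] <- mean(g[[v]])
        row[[paste0(v, "_sem")]] <- sd(g[[v]]) / sqrt(nrow(g))
      }
      row
    }))
    summ <- summ[order(summ$cohort, summ$bin_index), ]
    rownames(summ) <- NULL
    write.csv(summ, file.path(outdir, paste0("summary_", nm, ".csv")),
              row.names = FALSE)
    out[[nm]] <- summ
  }
  if (!found) stop_domain("run_report: no endpoint tables found in %s", results_dir)
  invisible(out)
}
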