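#' Compute every index for one subject-run session
#'
#' EDA indices use the first 120 s of the EDA record (SCL and NSSCRs from
#' the tonic/phasic decomposition; EDASymp/EDASympn and TVSymp from the
#' 2 Hz downsampled record); HRV indices use the first 240 s of ECG
#' through band-pass, R-peak detection, RR correction and 4 Hz spline
#' resampling; performance indices come from the trial log.  A failure in
#' one index group (e.g. an ECG segment rejected for artifacts) yields
#' explicit `NA`s for that group, with a warning, never silent zeros.
#'
#' @param session a [run_session()].
#' @param cfg an [analysis_config()].
#' @param eda_window_s,ecg_window_s analysis segment lengths, s.
#' @return One-row data.frame: `subject_id`, `run_number`,
#'   `hours_deprived`, then the [index_columns()].
#' @export
session_indices <- function(session, cfg = analysis_config(),
                            eda_window_s = 120, ecg_window_s = 240) {
  stopifnot(inherits(session, "run_session"))
  out <- data.frame(subject_id = session$subject_id,
                    run_number = session$run_number,
                    hours_deprived = session$hours_deprived,
                    stringsAsFactors = FALSE)
  for (col in index_columns()) out[[col]] <- NA_real_

  eda <- crop_record(session$eda, eda_window_s)
  eda_res <- try({
    dec <- decompose_eda(eda, cfg, min_duration_s = eda_window_s)
    events <- detect_scrs(dec, cfg = cfg)
    eda2 <- downsample_eda(eda, cfg$eda_fs_spectral)
    es <- edasymp(eda2, cfg)
    list(SCL = scl(dec, eda_window_s),
         NSSCRs = nsscr_index(events, eda_window_s, t0 = eda$t0),
         EDASymp = es$EDASymp, EDASympn = es$EDASympn,
         TVSymp = tvsymp(eda2, cfg))
  }, silent = TRUE)
  if (inherits(eda_res, "try-error")) {
    warning("EDA indices unavailable for ", session$subject_id, " run ",
            session$run_number, ": ", attr(eda_res, "condition")$message,
            call. = FALSE)
  } else {
    out[names(eda_res)] <- eda_res
  }

  ecg <- crop_record(session$ecg, ecg_window_s)
  hrv <- try(ecg_to_hrv(ecg, cfg), silent = TRUE)
  if (inherits(hrv, "try-error")) {
    warning("HRV indices unavailable for ", session$subject_id, " run ",
            session$run_number, ": ", attr(hrv, "condition")$message,
            call. = FALSE)
  } else {
    out[c("HRVLF", "HRVLFn", "HRVHF", "HRVHFn")] <-
      hrv[c("HRVLF", "HRVLFn", "HRVHF", "HRVHFn")]
  }

  perf <- try(performance_indices(session$trials), silent = TRUE)
  if (inherits(perf, "try-error")) {
    warning("performance indices unavailable for ", session$subject_id,
            " run ", session$run_number, ": ",
            attr(perf, "condition")$message, call. = FALSE)
  } else {
    out[c("Go_RT", "Stroop_NoGo_acc", "Repeat_NoGo_acc")] <-
      perf[c("Go_RT", "Stroop_NoGo_acc", "Repeat_NoGo_acc")]
  }
  out
}

crop_record <- function(x, window_s) {
  n <- as.integer(round(window_s * x$fs))
  if (n >= length(x$samples)) return(x)
  signal_record(x$samples[seq_len(n)], x$fs, units = x$units,
                label = x$label, t0 = x$t0)
}

#' Compute the per-run index table for a list of sessions
#'
#' @param sessions list of [run_session()] objects.
#' @param cfg an [analysis_config()].
#' @return data.frame with one row per session (see [session_indices()]).
#' @export
compute_index_table <- function(sessions, cfg = analysis_config()) {
  rows <- lapply(sessions, session_indices, cfg = cfg)
  do.call(rbind, rows)
}

#' Write a simulated cohort to signal files and trial logs
#'
#' Creates `<dir>/<subject>_run<RR>_{eda,ecg}.csv` and
#' `<dir>/<subject>_run<RR>_trials.csv` for every session.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort_files <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$sessions) {
    stem <- file.path(dir, sprintf("%s_run%02d", s$subject_id,
                                   s$run_number))
    write_signal_csv(s$eda, paste0(stem, "_eda.csv"))
    write_signal_csv(s$ecg, paste0(stem, "_ecg.csv"))
    write_trial_log(s$trials, paste0(stem, "_trials.csv"))
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort_files()]
#'
#' @param dir directory containing `*_eda.csv`, `*_ecg.csv`,
#'   `*_trials.csv` triplets.
#' @param hours_convention run/hour convention (see [hours_awake()]).
#' @return List of [run_session()] objects.
#' @export
read_cohort_files <- function(dir,
                              hours_convention = c("arrival",
                                                   "deprivation")) {
  hours_convention <- match.arg(hours_convention)
  eda_files <- sort(list.files(dir, "_eda\\.csv$", full.names = TRUE))
  if (!length(eda_files))
    stop("no *_eda.csv files found in ", dir, call. = FALSE)
  lapply(eda_files, function(f) {
    stem <- sub("_eda\\.csv$", "", f)
    m <- regmatches(basename(stem),
                    regexec("^(.*)_run([0-9]+)$", basename(stem)))[[1]]
    if (length(m) != 3)
      stop("cannot parse subject/run from ", basename(f), call. = FALSE)
    run_session(m[2], as.integer(m[3]),
                eda = read_signal_csv(f),
                ecg = read_signal_csv(paste0(stem, "_ecg.csv")),
                trials = read_trial_log(paste0(stem, "_trials.csv")),
                hours_convention = hours_convention)
  })
}
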