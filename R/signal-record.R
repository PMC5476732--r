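#' Uniformly sampled physiological signal
#'
#' The basic container used throughout the pipeline: a numeric sample
#' vector with its sampling rate, physical units, a channel label, and a
#' start offset.  EDA channels are in microsiemens (uS), ECG in millivolts.
#'
#' @param samples numeric vector of sample values.
#' @param fs sampling rate in Hz (> 0).
#' @param units physical units of the samples, e.g. `"uS"` or `"mV"`.
#' @param label channel label, e.g. `"eda"` or `"ecg"`.
#' @param t0 start time offset in seconds (default 0).
#'
#' @return An object of class `"signal_record"` with fields `samples`,
#'   `fs`, `units`, `label`, `t0`.
#' @examples
#' x <- signal_record(sin(2 * pi * 1 * (0:399) / 400), fs = 400, units = "mV")
#' duration(x)
#' @export
signal_record <- function(samples, fs, units = "", label = "", t0 = 0) {
  if (!is.numeric(samples) || length(samples) == 0)
    stop("samples must be a non-empty numeric vector", call. = FALSE)
  if (anyNA(samples))
    stop("samples must not contain missing values", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number", call. = FALSE)
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         units = as.character(units), label = as.character(label),
         t0 = as.numeric(t0)),
    class = "signal_record"
  )
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> %s: %d samples @ %g Hz (%.2f s) [%s]\n",
              if (nzchar(x$label)) x$label else "unlabelled",
              length(x$samples), x$fs, duration(x), x$units))
  invisible(x)
}

#' Duration of a signal record in seconds
#' @param x a [signal_record()].
#' @return Duration `length(samples) / fs` in seconds.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "signal_record"))
  length(x$samples) / x$fs
}

#' Sample time axis of a signal record
#' @param x a [signal_record()].
#' @return Numeric vector of sample times in seconds (starting at `t0`).
#' @export
time_axis <- function(x) {
  stopifnot(inherits(x, "signal_record"))
  x$t0 + (seq_along(x$samples) - 1) / x$fs
}

#' One behavioural trial of the go/no-go task
#'
#' @param index trial number within the run (1-based).
#' @param kind one of `"GO"`, `"STROOP_NOGO"`, `"REPEAT_NOGO"`.
#' @param onset_s stimulus onset in seconds from run start.
#' @param responded logical: did the subject press the button?
#' @param rt_ms reaction time in ms; must be present iff `responded`.
#' @return A `"task_trial"` list.
#' @export
task_trial <- function(index, kind, onset_s, responded, rt_ms = NA_real_) {
  kind <- match.arg(kind, trial_kinds())
  responded <- isTRUE(responded)
  if (responded && (is.na(rt_ms) || rt_ms <= 0))
    stop("responded trials must carry a positive rt_ms", call. = FALSE)
  if (!responded && !is.na(rt_ms))
    stop("rt_ms must be absent when the trial was not responded",
         call. = FALSE)
  structure(list(index = as.integer(index), kind = kind,
                 onset_s = as.numeric(onset_s), responded = responded,
                 rt_ms = as.numeric(rt_ms)),
            class = "task_trial")
}

#' Valid trial kinds
#' @return Character vector of the three trial kinds.
#' @export
trial_kinds <- function() c("GO", "STROOP_NOGO", "REPEAT_NOGO")

#' Convert a list of trials to a data frame
#' @param trials list of [task_trial()] objects.
#' @return data.frame with one row per trial.
#' @export
trials_to_df <- function(trials) {
  stopifnot(all(vapply(trials, inherits, logical(1), "task_trial")))
  data.frame(
    index = vapply(trials, `[[`, integer(1), "index"),
    kind = vapply(trials, `[[`, character(1), "kind"),
    onset_s = vapply(trials, `[[`, numeric(1), "onset_s"),
    responded = vapply(trials, `[[`, logical(1), "responded"),
    rt_ms = vapply(trials, `[[`, numeric(1), "rt_ms"),
    stringsAsFactors = FALSE
  )
}

#' One subject-run recording bundle
#'
#' Couples the EDA and ECG segments recorded during one run of the task
#' with the trial log and the run's position in the deprivation protocol.
#'
#' @param subject_id subject identifier.
#' @param run_number run index, 1..13 under the default protocol.
#' @param eda EDA [signal_record()] (uS); indices use a 120 s segment.
#' @param ecg ECG [signal_record()] (mV); indices use a 240 s segment.
#' @param trials list of [task_trial()] objects.
#' @param hours_deprived hours awake; if `NULL`, derived from `run_number`
#'   via `hours_convention`.
#' @param hours_convention `"arrival"`: hours = 2*(run-1) (run 1 on
#'   arrival); `"deprivation"`: hours = 2*run.
#' @return A `"run_session"` list.
#' @export
run_session <- function(subject_id, run_number, eda, ecg, trials,
                        hours_deprived = NULL,
                        hours_convention = c("arrival", "deprivation")) {
  hours_convention <- match.arg(hours_convention)
  run_number <- as.integer(run_number)
  if (run_number < 1) stop("run_number must be >= 1", call. = FALSE)
  stopifnot(inherits(eda, "signal_record"), inherits(ecg, "signal_record"))
  if (is.null(hours_deprived))
    hours_deprived <- hours_awake(run_number, hours_convention)
  if (hours_deprived < 0) stop("hours_deprived must be >= 0", call. = FALSE)
  structure(list(subject_id = as.character(subject_id),
                 run_number = run_number,
                 hours_deprived = as.numeric(hours_deprived),
                 eda = eda, ecg = ecg, trials = trials),
            class = "run_session")
}

#' Hours awake implied by a run number
#'
#' Runs take place every other hour.  Under the `"arrival"` convention run
#' 1 happens on arrival (0 h awake in-protocol) so hours = 2*(run-1); the
#' `"deprivation"` convention counts hours = 2*run.  The protocol's own
#' bookkeeping admits both readings, so neither is asserted as the true
#' one; the convention is explicit everywhere it matters.
#'
#' @param run_number integer run index (vectorised).
#' @param convention `"arrival"` (default) or `"deprivation"`.
#' @return Hours awake.
#' @export
hours_awake <- function(run_number, convention = c("arrival", "deprivation")) {
  convention <- match.arg(convention)
  if (convention == "arrival") 2 * (run_number - 1) else 2 * run_number
}

#' @export
print.run_session <- function(x, ...) {
  cat(sprintf("<run_session> subject %s run %d (%g h awake): %d trials\n",
              x$subject_id, x$run_number, x$hours_deprived, length(x$trials)))
  print(x$eda); print(x$ecg)
  invisible(x)
}

#' Column order of the per-run index table
#' @return Character vector naming the index columns in canonical order.
#' @export
index_columns <- function() {
  c("HRVLF", "HRVLFn", "HRVHF", "HRVHFn", "SCL", "NSSCRs",
    "EDASymp", "EDASympn", "TVSymp", "Go_RT",
    "Stroop_NoGo_acc", "Repeat_NoGo_acc")
}
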