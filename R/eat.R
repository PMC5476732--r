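#' Per-run performance indices from a trial log
#'
#' `Go_RT` is the mean reaction time over responded Go trials; each
#' no-go accuracy is the fraction of trials of that kind on which the
#' response was withheld.  Responses are only counted inside the response
#' window (stimulus plus inter-stimulus interval, 1500 ms): later presses
#' are treated as misses by the log producer.
#'
#' @param trials list of [task_trial()] objects containing at least one
#'   trial of each kind.
#' @return A `"performance_indices"` list: `Go_RT` (ms),
#'   `Stroop_NoGo_acc`, `Repeat_NoGo_acc` (fractions in `[0,1]`), and the
#'   per-kind trial counts `n_go`, `n_stroop`, `n_repeat`.
#' @examples
#' trials <- c(
#'   lapply(1:3, function(i)
#'     task_trial(i, "GO", 1.5 * i, TRUE, rt_ms = 100 * i + 300)),
#'   list(task_trial(4, "STROOP_NOGO", 6, FALSE),
#'        task_trial(5, "REPEAT_NOGO", 7.5, FALSE))
#' )
#' performance_indices(trials)
#' @export
performance_indices <- function(trials) {
  df <- trials_to_df(trials)
  missing_kinds <- setdiff(trial_kinds(), unique(df$kind))
  if (length(missing_kinds))
    stop("trial log has no trials of kind: ",
         paste(missing_kinds, collapse = ", "), call. = FALSE)
  go <- df[df$kind == "GO", ]
  stroop <- df[df$kind == "STROOP_NOGO", ]
  rept <- df[df$kind == "REPEAT_NOGO", ]
  responded_go <- go[go$responded, ]
  if (nrow(responded_go) == 0)
    stop("no responded Go trials: Go_RT undefined", call. = FALSE)
  structure(list(
    Go_RT = mean(responded_go$rt_ms),
    Stroop_NoGo_acc = mean(!stroop$responded),
    Repeat_NoGo_acc = mean(!rept$responded),
    n_go = nrow(go), n_stroop = nrow(stroop), n_repeat = nrow(rept)
  ), class = "performance_indices")
}

#' @export
print.performance_indices <- function(x, ...) {
  cat(sprintf(
    "<performance_indices> Go_RT %.0f ms; Stroop acc %.2f (n=%d); Repeat acc %.2f (n=%d)\n",
    x$Go_RT, x$Stroop_NoGo_acc, x$n_stroop, x$Repeat_NoGo_acc, x$n_repeat))
  invisible(x)
}
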