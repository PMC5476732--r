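#' Read a single-channel signal file
#'
#' The on-disk signal format is deliberately minimal: UTF-8 text, comment
#' header lines of the form `# key=value` carrying `fs_hz` (required),
#' `units`, `label` and `t0_s`, followed by one numeric sample per line.
#'
#' @param path file path.
#' @return A [signal_record()].
#' @seealso [write_signal_csv()]
#' @export
read_signal_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_hdr <- grepl("^#", lines)
  hdr <- lines[is_hdr]
  body <- lines[!is_hdr]
  body <- body[nzchar(trimws(body))]

  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*)$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  if (is.null(meta$fs_hz))
    stop("signal file header missing fs_hz: ", path, call. = FALSE)
  fs <- suppressWarnings(as.numeric(meta$fs_hz))
  if (is.na(fs) || fs <= 0)
    stop("invalid fs_hz header in ", path, call. = FALSE)
  if (length(body) == 0)
    stop("signal file has an empty data section: ", path, call. = FALSE)

  samples <- suppressWarnings(as.numeric(body))
  if (anyNA(samples)) {
    bad <- which(is.na(samples))[1]
    # report the physical line number of the offending row
    line_no <- which(!is_hdr)[bad]
    stop(sprintf("non-numeric sample at line %d of %s: '%s'",
                 line_no, path, body[bad]), call. = FALSE)
  }
  signal_record(samples, fs = fs,
                units = if (is.null(meta$units)) "" else meta$units,
                label = if (is.null(meta$label)) "" else meta$label,
                t0 = if (is.null(meta$t0_s)) 0 else as.numeric(meta$t0_s))
}

#' Write a single-channel signal file
#'
#' @param x a [signal_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_signal_csv()]
#' @export
write_signal_csv <- function(x, path) {
  stopifnot(inherits(x, "signal_record"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fs_hz=%s", format(x$fs, digits = 17)),
    sprintf("# units=%s", x$units),
    sprintf("# label=%s", x$label),
    sprintf("# t0_s=%s", format(x$t0, digits = 17)),
    format(x$samples, digits = 17, scientific = TRUE, trim = TRUE)
  ), con)
  invisible(path)
}

#' Read a trial log
#'
#' CSV with columns `index,kind,onset_s,responded,rt_ms`; `rt_ms` is empty
#' for unresponded trials.  Trials are returned sorted by onset and each
#' `kind` is validated against the three-trial taxonomy.
#'
#' @param path file path.
#' @return List of [task_trial()] objects sorted by onset.
#' @export
read_trial_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("index", "kind", "onset_s", "responded", "rt_ms")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("trial log missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  bad_kind <- setdiff(unique(df$kind), trial_kinds())
  if (length(bad_kind))
    stop("unknown trial kind(s): ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  df <- df[order(df$onset_s), , drop = FALSE]
  lapply(seq_len(nrow(df)), function(i) {
    task_trial(df$index[i], df$kind[i], df$onset_s[i],
               as.logical(df$responded[i]),
               if (is.na(df$rt_ms[i])) NA_real_ else df$rt_ms[i])
  })
}

#' Write a trial log
#' @param trials list of [task_trial()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path) {
  df <- trials_to_df(trials)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write the per-run index table
#'
#' One row per (subject, run); columns in the canonical [index_columns()]
#' order.  Missing values are written as empty cells, never as zero.
#'
#' @param table data.frame with columns `subject_id`, `run_number` and the
#'   index columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_index_table <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0)
    stop("index table must be a non-empty data.frame", call. = FALSE)
  cols <- c("subject_id", "run_number",
            intersect(index_columns(), names(table)))
  if (anyDuplicated(table[c("subject_id", "run_number")]))
    stop("index table must have one row per (subject, run)", call. = FALSE)
  out <- table[cols]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    ifelse(is.na(v), "", format(v, digits = 15, trim = TRUE))
  })
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a per-run index table written by [write_index_table()]
#' @param path file path.
#' @return data.frame with `subject_id`, `run_number` and index columns;
#'   empty cells become `NA`.
#' @export
read_index_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  for (cl in setdiff(names(df), "subject_id")) df[[cl]] <- as.numeric(df[[cl]])
  df$run_number <- as.integer(df$run_number)
  df
}
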