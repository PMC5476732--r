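#' Analysis configuration
#'
#' Bundles every fixed constant of the index pipeline into a validated list
#' so that each one can be overridden in a single place.  Defaults are the
#' study's analysis settings: spectral HRV bands of the Task Force
#' standard, the sudomotor EDA band, the 0.05 uS skin-conductance-response
#' threshold, Welch window lengths, and the alpha level of the rank
#' analysis.
#'
#' @param ... named overrides for any of the fields listed below.
#'
#' @return An object of class `"analysis_config"`: a named list with fields
#'   \describe{
#'     \item{hrv_lf_band}{low-frequency HRV band, Hz (default 0.045-0.15)}
#'     \item{hrv_hf_band}{high-frequency HRV band, Hz (default 0.15-0.4)}
#'     \item{edasymp_band}{EDA sympathetic band, Hz (default 0.045-0.25)}
#'     \item{tvsymp_band}{TVSymp component band, Hz (default 0.08-0.24)}
#'     \item{scr_threshold}{minimum SCR trough-to-peak rise, uS (0.05)}
#'     \item{tonic_method}{tonic extraction: "moving_mean" or "fir"}
#'     \item{tonic_fir_order}{order of the verbatim tonic FIR filter (10)}
#'     \item{tonic_cutoff}{its cutoff frequency, Hz (0.0004)}
#'     \item{tonic_span_s}{span of the moving-mean detrender, s (20)}
#'     \item{eda_fs_spectral}{EDA rate for spectral indices, Hz (2)}
#'     \item{rr_resample_fs}{RR resampling rate, Hz (4)}
#'     \item{welch_overlap}{Welch segment overlap fraction (0.5)}
#'     \item{hrv_window_len}{Welch window for HRV, samples (256)}
#'     \item{eda_window_len}{Welch window for EDA, samples (128)}
#'     \item{welch_window}{taper name (\"blackman\")}
#'     \item{vfcdm_band_width}{VFCDM band width Fw, Hz (0.08)}
#'     \item{scr_min_rise_s}{minimum SCR rise time, s (0.5)}
#'     \item{scr_refractory_s}{minimum spacing between SCR onsets, s (1)}
#'     \item{scr_smooth_s}{pre-detection smoothing span, s (0.25)}
#'     \item{rr_median_width}{running-median width for RR cleaning (5)}
#'     \item{rr_low,rr_high}{acceptance factors around the running median
#'       (0.66, 1.5)}
#'     \item{rr_max_corrected}{fraction of corrected intervals above which a
#'       segment is rejected (0.2)}
#'     \item{posthoc_method}{"nemenyi" (default) or "bonferroni"}
#'     \item{alpha}{significance level (0.05)}
#'     \item{hours_convention}{"arrival" (hours awake = 2*(run-1)) or
#'       "deprivation" (= 2*run)}
#'   }
#' @examples
#' cfg <- analysis_config(scr_threshold = 0.04)
#' cfg$hrv_lf_band
#' @export
analysis_config <- function(...) {
  cfg <- list(
    hrv_lf_band    = c(0.045, 0.15),
    hrv_hf_band    = c(0.15, 0.4),
    edasymp_band   = c(0.045, 0.25),
    tvsymp_band    = c(0.08, 0.24),
    scr_threshold  = 0.05,
    tonic_method   = "moving_mean",
    tonic_fir_order = 10,
    tonic_cutoff   = 4e-4,
    tonic_span_s   = 20,
    eda_fs_spectral = 2,
    rr_resample_fs = 4,
    welch_overlap  = 0.5,
    hrv_window_len = 256L,
    eda_window_len = 128L,
    welch_window   = "blackman",
    vfcdm_band_width = 0.08,
    scr_min_rise_s = 0.5,
    scr_refractory_s = 1,
    scr_smooth_s   = 0.25,
    rr_median_width = 5L,
    rr_low         = 0.66,
    rr_high        = 1.5,
    rr_max_corrected = 0.2,
    posthoc_method = "nemenyi",
    alpha          = 0.05,
    hours_convention = "arrival"
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots))))
      stop("config overrides must be named", call. = FALSE)
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown config field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_config <- function(cfg) {
  for (band in c("hrv_lf_band", "hrv_hf_band", "edasymp_band", "tvsymp_band")) {
    b <- cfg[[band]]
    if (length(b) != 2 || any(b <= 0) || b[1] >= b[2])
      stop(band, " must be two positive increasing edges", call. = FALSE)
  }
  stopifnot(
    cfg$scr_threshold > 0,
    cfg$tonic_cutoff > 0,
    cfg$eda_fs_spectral > 0,
    cfg$rr_resample_fs > 0,
    cfg$welch_overlap >= 0, cfg$welch_overlap < 1,
    cfg$hrv_window_len >= 8, cfg$eda_window_len >= 8,
    cfg$alpha > 0, cfg$alpha < 1
  )
  # bands must lie below the Nyquist of the series they are applied to
  if (cfg$hrv_hf_band[2] > cfg$rr_resample_fs / 2)
    stop("HRV HF band exceeds RR Nyquist frequency", call. = FALSE)
  if (cfg$edasymp_band[2] > cfg$eda_fs_spectral / 2)
    stop("EDASymp band exceeds spectral-EDA Nyquist frequency", call. = FALSE)
  if (cfg$tvsymp_band[2] > cfg$eda_fs_spectral / 2)
    stop("TVSymp band exceeds spectral-EDA Nyquist frequency", call. = FALSE)
  cfg$tonic_method <- match.arg(cfg$tonic_method, c("moving_mean", "fir"))
  cfg$posthoc_method <- match.arg(cfg$posthoc_method, c("nemenyi", "bonferroni"))
  cfg$hours_convention <- match.arg(cfg$hours_convention,
                                    c("arrival", "deprivation"))
  invisible(cfg)
}

#' Read a key/value configuration file
#'
#' Plain-text configuration: one `key = value` pair per line, `#` comments.
#' Vector-valued fields (the bands) are given as comma-separated numbers.
#'
#' @param path file path.
#' @return An [analysis_config()] with the file's overrides applied.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  overrides <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("malformed config line: '", ln, "'", call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    overrides[[key]] <- if (anyNA(num)) val else num
  }
  do.call(analysis_config, overrides)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
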