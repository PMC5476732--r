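#' Band-pass filter an ECG record
#'
#' Zero-phase (forward-backward) 0.05-40 Hz band-pass to remove baseline
#' wander and high-frequency noise ahead of R-peak detection.  Implemented
#' as a high-pass/low-pass Butterworth cascade applied forwards and
#' backwards, so the output has no group delay and the same length and
#' rate as the input.
#'
#' @param ecg an ECG [signal_record()]; `fs` must exceed 80 Hz so the 40 Hz
#'   passband edge stays below Nyquist.
#' @param lo,hi passband edges in Hz.
#' @return Filtered [signal_record()].
#' @export
bandpass_ecg <- function(ecg, lo = 0.05, hi = 40) {
  stopifnot(inherits(ecg, "signal_record"))
  if (ecg$fs <= 2 * hi)
    stop(sprintf("sampling rate %g Hz too low for a %g Hz passband edge",
                 ecg$fs, hi), call. = FALSE)
  y <- butter_bandpass_zp(ecg$samples, ecg$fs, lo, hi)
  signal_record(y, fs = ecg$fs, units = ecg$units, label = ecg$label,
                t0 = ecg$t0)
}

#' Detect R peaks with an envelope delineation function
#'
#' The delineation function is the magnitude of the analytic signal of a
#' QRS-band (5-25 Hz) copy of the ECG.  Candidate beats are local maxima
#' of this envelope exceeding an adaptive threshold (half the trailing
#' 2-s envelope maximum); a refractory period suppresses double firing,
#' and each detection is refined to the raw-ECG maximum within +/- 50 ms.
#'
#' @param ecg a band-passed ECG [signal_record()], duration >= 10 s.
#' @param qrs_band QRS passband in Hz (default `c(5, 25)`).
#' @param threshold_frac fraction of the trailing envelope maximum used as
#'   detection threshold (default 0.5).
#' @param trailing_s trailing window for the adaptive threshold, s (2).
#' @param floor_frac fraction of the global envelope maximum used as a
#'   threshold floor, guarding the warm-up region before the first beat
#'   where the trailing window contains only noise (default 0.2).
#' @param refractory_s minimum beat spacing, s (0.25).
#' @param refine_s half-width of the raw-maximum refinement window, s (0.05).
#'
#' @return A `"beat_series"`: list with `beat_times_s` (strictly
#'   increasing), `rr_ms` (successive differences x 1000) and
#'   `corrected_flags` (all `FALSE`; see [clean_rr()]).  Empty series if
#'   nothing crosses threshold.
#' @export
detect_r_peaks <- function(ecg, qrs_band = c(5, 25), threshold_frac = 0.5,
                           trailing_s = 2, refractory_s = 0.25,
                           refine_s = 0.05, floor_frac = 0.2) {
  stopifnot(inherits(ecg, "signal_record"))
  if (duration(ecg) < 10)
    stop("R-peak detection needs at least 10 s of ECG", call. = FALSE)
  fs <- ecg$fs
  x <- ecg$samples
  n <- length(x)

  qrs <- butter_bandpass_zp(x, fs, qrs_band[1], qrs_band[2],
                            order_lo = 2, order_hi = 2)
  env <- Mod(analytic_signal(qrs))

  w <- max(2L, as.integer(round(trailing_s * fs)))
  thr <- pmax(threshold_frac * run_max_trailing(env, w),
              floor_frac * max(env))

  if (max(env) <= 0 || all(env < thr)) return(beat_series(numeric(0)))

  is_peak <- c(FALSE, diff(env) > 0) & c(diff(env) < 0, FALSE) & env >= thr
  cand <- which(is_peak)
  if (!length(cand)) return(beat_series(numeric(0)))

  refr <- as.integer(round(refractory_s * fs))
  kept <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= refr) {
      kept <- c(kept, i)
      last <- i
    } else if (env[i] > env[kept[length(kept)]]) {
      # stronger peak inside the refractory window replaces the weaker one
      kept[length(kept)] <- i
      last <- i
    }
  }

  half <- as.integer(round(refine_s * fs))
  peaks <- vapply(kept, function(i) {
    a <- max(1L, i - half)
    b <- min(n, i + half)
    a + which.max(x[a:b]) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))
  # refinement can merge neighbours onto one raw maximum; keep it single
  beat_series(ecg$t0 + (peaks - 1) / fs)
}

#' Construct a beat series from beat times
#' @param beat_times_s strictly increasing beat times in seconds.
#' @param corrected_flags optional per-interval logical flags.
#' @return A `"beat_series"` object.
#' @export
beat_series <- function(beat_times_s,
                        corrected_flags = rep(FALSE,
                                              max(0, length(beat_times_s) - 1))) {
  beat_times_s <- as.numeric(beat_times_s)
  if (is.unsorted(beat_times_s, strictly = TRUE))
    stop("beat times must be strictly increasing", call. = FALSE)
  rr <- diff(beat_times_s) * 1000
  if (any(rr <= 0)) stop("all RR intervals must be positive", call. = FALSE)
  stopifnot(length(corrected_flags) == length(rr))
  structure(list(beat_times_s = beat_times_s, rr_ms = rr,
                 corrected_flags = corrected_flags),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats, %d corrected interval(s)\n",
              length(x$beat_times_s), sum(x$corrected_flags)))
  invisible(x)
}

#' Automated ectopic/artifact correction of an RR series
#'
#' Replaces manual beat inspection with a reproducible rule: an interval
#' falling outside `[low, high]` times the running 5-interval median is
#' flagged and replaced by interpolating RR across the neighbouring clean
#' intervals.  Segments where more than `max_frac` of intervals need
#' correction are rejected, mirroring the requirement for clean ECG.
#'
#' @param beats a `"beat_series"` with at least 6 beats.
#' @param low,high acceptance band as multiples of the running median
#'   (defaults 0.66 and 1.5).
#' @param width running-median width in intervals (odd; default 5).
#' @param max_frac maximum tolerated fraction of corrected intervals (0.2).
#' @return A `"beat_series"` with corrected `rr_ms` and `corrected_flags`
#'   marking replaced intervals; beat times are rebuilt from the corrected
#'   intervals anchored at the first beat.
#' @export
clean_rr <- function(beats, low = 0.66, high = 1.5, width = 5,
                     max_frac = 0.2) {
  stopifnot(inherits(beats, "beat_series"))
  if (length(beats$beat_times_s) < 6)
    stop("RR cleaning needs at least 6 beats", call. = FALSE)
  rr <- beats$rr_ms
  if (width %% 2 == 0) width <- width + 1
  med <- as.numeric(stats::runmed(rr, width, endrule = "median"))
  bad <- rr < low * med | rr > high * med
  frac <- mean(bad)
  if (frac > max_frac)
    stop(sprintf("segment rejected: %.0f%% of intervals flagged (limit %.0f%%)",
                 100 * frac, 100 * max_frac), call. = FALSE)
  if (any(bad)) {
    idx <- seq_along(rr)
    if (sum(!bad) < 2)
      stop("too few clean intervals to interpolate", call. = FALSE)
    rr[bad] <- stats::approx(idx[!bad], rr[!bad], xout = idx[bad],
                             rule = 2)$y
  }
  times <- beats$beat_times_s[1] + c(0, cumsum(rr)) / 1000
  beat_series(times, corrected_flags = bad)
}

#' Resample an RR series to a uniform rate by cubic splines
#'
#' Each interval is indexed by the time of its terminating beat; a cubic
#' spline through (beat time, RR) is evaluated on a uniform grid at
#' `fs_out` covering the beat-time span.
#'
#' @param beats a `"beat_series"` with at least 4 intervals.
#' @param fs_out output rate in Hz (default 4).
#' @return A [signal_record()] of RR values in ms at `fs_out`; `t0` is the
#'   time of the first interval's terminating beat.
#' @export
resample_rr <- function(beats, fs_out = 4) {
  stopifnot(inherits(beats, "beat_series"))
  rr <- beats$rr_ms
  if (length(rr) < 4)
    stop("RR resampling needs at least 4 intervals", call. = FALSE)
  tt <- beats$beat_times_s[-1]
  t_first <- beats$beat_times_s[1]
  span <- tt[length(tt)] - t_first
  n_out <- floor(span * fs_out)
  if (n_out < 1) stop("beat-time span too short to resample", call. = FALSE)
  grid <- t_first + (0:(n_out - 1)) / fs_out
  sp <- stats::splinefun(tt, rr, method = "fmm")
  signal_record(sp(grid), fs = fs_out, units = "ms", label = "rr",
                t0 = t_first)
}

#' Spectral HRV indices
#'
#' Welch PSD (Blackman window of `cfg$hrv_window_len` samples, 50%
#' overlap) of the de-meaned uniformly resampled RR series; `HRVLF` and
#' `HRVHF` are the band powers over the configured LF (0.045-0.15 Hz) and
#' HF (0.15-0.4 Hz) bands in ms^2, and the normalized indices divide by
#' the total power over `(0, fs/2]`.
#'
#' @param rr4 RR [signal_record()] at `cfg$rr_resample_fs` Hz, at least
#'   one window long.
#' @param cfg an [analysis_config()].
#' @return An `"hrv_indices"` list: `HRVLF`, `HRVHF` (ms^2), `HRVLFn`,
#'   `HRVHFn` (normalized units in `[0,1]`), `total_power` (ms^2).
#' @export
hrv_indices <- function(rr4, cfg = analysis_config()) {
  stopifnot(inherits(rr4, "signal_record"))
  if (abs(rr4$fs - cfg$rr_resample_fs) > 1e-9)
    stop(sprintf("expected a %g Hz RR series, got %g Hz",
                 cfg$rr_resample_fs, rr4$fs), call. = FALSE)
  spec <- welch_psd(rr4, cfg$hrv_window_len, cfg$welch_overlap,
                    cfg$welch_window)
  lf <- band_power(spec, cfg$hrv_lf_band[1], cfg$hrv_lf_band[2])
  hf <- band_power(spec, cfg$hrv_hf_band[1], cfg$hrv_hf_band[2])
  tot <- total_power(spec)
  if (tot <= 0)
    stop("zero total HRV power: normalized indices undefined", call. = FALSE)
  structure(list(HRVLF = lf, HRVHF = hf, HRVLFn = lf / tot,
                 HRVHFn = hf / tot, total_power = tot),
            class = "hrv_indices")
}

#' @export
print.hrv_indices <- function(x, ...) {
  cat(sprintf(
    "<hrv_indices> LF %.3g ms^2 (%.3f n.u.), HF %.3g ms^2 (%.3f n.u.)\n",
    x$HRVLF, x$HRVLFn, x$HRVHF, x$HRVHFn))
  invisible(x)
}

#' Full ECG-to-HRV pipeline for one record
#'
#' Band-pass, R-peak detection, automated RR correction, 4 Hz spline
#' resampling, and spectral indices.
#'
#' @param ecg raw ECG [signal_record()].
#' @param cfg an [analysis_config()].
#' @return An `"hrv_indices"` object.
#' @export
ecg_to_hrv <- function(ecg, cfg = analysis_config()) {
  filtered <- bandpass_ecg(ecg)
  beats <- detect_r_peaks(filtered)
  beats <- clean_rr(beats, low = cfg$rr_low, high = cfg$rr_high,
                    width = cfg$rr_median_width,
                    max_frac = cfg$rr_max_corrected)
  rr4 <- resample_rr(beats, cfg$rr_resample_fs)
  hrv_indices(rr4, cfg)
}
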