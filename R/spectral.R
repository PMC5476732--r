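#' Welch power spectral density
#'
#' Averaged-periodogram PSD estimate: the record is cut into full,
#' overlapping segments of `window_len` samples starting at multiples of
#' `window_len * (1 - overlap)`; each segment is de-meaned, tapered, and
#' transformed; the one-sided periodograms are averaged.  The density is
#' normalized for the taper's power so that the Riemann sum
#' `sum(density) * df` over `[0, fs/2]` estimates the signal variance.
#' Partial trailing segments are dropped and no zero-padding is applied:
#' the transform length equals the window length.
#'
#' @param x a [signal_record()] (or plain numeric vector with `fs` given).
#' @param window_len segment length in samples.
#' @param overlap overlap fraction in `[0, 1)` (default 0.5).
#' @param window_kind taper name: `"blackman"` (default), `"hamming"`,
#'   `"hann"` or `"rectangular"`.
#' @param fs sampling rate, only when `x` is a bare numeric vector.
#'
#' @return An object of class `"power_spectrum"`: list with `freqs` (Hz,
#'   `0` to `fs/2`, spacing `fs / window_len`), `density` (input-units^2
#'   per Hz), `fs`, `window_len`, `n_segments`, `df`.
#' @examples
#' set.seed(1)
#' x <- signal_record(rnorm(960), fs = 4)
#' ps <- welch_psd(x, 256)
#' sum(ps$density) * ps$df  # ~ 1
#' @export
welch_psd <- function(x, window_len, overlap = 0.5,
                      window_kind = "blackman", fs = NULL) {
  if (inherits(x, "signal_record")) {
    fs <- x$fs
    x <- x$samples
  }
  if (is.null(fs)) stop("fs required when x is not a signal_record",
                        call. = FALSE)
  window_len <- as.integer(window_len)
  n <- length(x)
  if (n < window_len)
    stop(sprintf("record (%d samples) shorter than one window (%d)",
                 n, window_len), call. = FALSE)
  if (overlap < 0 || overlap >= 1)
    stop("overlap must be in [0, 1)", call. = FALSE)

  w <- taper_window(window_len, window_kind)
  step <- max(1L, as.integer(round(window_len * (1 - overlap))))
  starts <- seq.int(1L, n - window_len + 1L, by = step)

  n_half <- window_len %/% 2L
  acc <- numeric(n_half + 1L)
  scale <- 1 / (fs * sum(w^2))
  for (s in starts) {
    seg <- x[s:(s + window_len - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg))^2 * scale
    one <- P[1:(n_half + 1L)]
    # double the interior bins to fold negative frequencies in
    if (window_len %% 2L == 0L) {
      if (n_half > 1L) one[2:n_half] <- 2 * one[2:n_half]
    } else {
      one[2:(n_half + 1L)] <- 2 * one[2:(n_half + 1L)]
    }
    acc <- acc + one
  }
  density <- acc / length(starts)
  df <- fs / window_len
  structure(list(freqs = (0:n_half) * df, density = density, fs = fs,
                 window_len = window_len, n_segments = length(starts),
                 df = df),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf(
    "<power_spectrum> %d bins, df = %g Hz, %d segment(s), total power %.4g\n",
    length(x$freqs), x$df, x$n_segments, sum(x$density) * x$df))
  invisible(x)
}

#' Band power of a spectrum
#'
#' Riemann sum of `density * df` over the bins whose center frequency `f`
#' satisfies `lo <= f < hi` (half-open, so adjacent bands sharing an edge
#' never double-count a bin).  Two deliberate boundary rules: the DC bin
#' is always excluded, and when `hi` equals the Nyquist frequency the
#' Nyquist bin is included so that bands partitioning `(0, fs/2]` sum to
#' the total power.
#'
#' @param spec a `"power_spectrum"` from [welch_psd()].
#' @param lo,hi band edges in Hz, `0 <= lo < hi <= fs/2`.
#' @return Band power in input-units^2 (non-negative scalar).
#' @export
band_power <- function(spec, lo, hi) {
  stopifnot(inherits(spec, "power_spectrum"))
  nyq <- spec$fs / 2
  tol <- spec$df * 1e-9
  if (lo < 0 || hi > nyq + tol || lo >= hi)
    stop(sprintf("invalid band [%g, %g): need 0 <= lo < hi <= fs/2 = %g",
                 lo, hi, nyq), call. = FALSE)
  f <- spec$freqs
  sel <- f > tol & f >= lo - tol & f < hi - tol
  if (abs(hi - nyq) <= tol) sel <- sel | abs(f - nyq) <= tol
  sum(spec$density[sel]) * spec$df
}

#' Total spectral power over (0, fs/2]
#' @param spec a `"power_spectrum"`.
#' @return Total power excluding the DC bin.
#' @export
total_power <- function(spec) band_power(spec, 0, spec$fs / 2)
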