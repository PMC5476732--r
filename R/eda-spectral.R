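#' Downsample EDA for spectral analysis
#'
#' Anti-alias low-pass (zero-phase Butterworth, cutoff 0.8 Hz) followed by
#' integer decimation to the target rate (2 Hz by convention).  The input
#' rate must be an integer multiple of `fs_out`.
#'
#' @param eda EDA [signal_record()].
#' @param fs_out target rate in Hz (default 2).
#' @param cutoff_hz anti-alias cutoff, must stay below `fs_out / 2`
#'   scaled margin (default 0.8).
#' @return Decimated [signal_record()] at `fs_out`.
#' @export
downsample_eda <- function(eda, fs_out = 2, cutoff_hz = 0.8) {
  stopifnot(inherits(eda, "signal_record"))
  if (eda$fs < fs_out)
    stop(sprintf("cannot downsample %g Hz to %g Hz", eda$fs, fs_out),
         call. = FALSE)
  if (abs(eda$fs - fs_out) < 1e-9) return(eda)
  factor <- eda$fs / fs_out
  if (abs(factor - round(factor)) > 1e-9)
    stop(sprintf("rate %g Hz is not an integer multiple of %g Hz",
                 eda$fs, fs_out), call. = FALSE)
  factor <- as.integer(round(factor))
  lp <- signal::butter(4, cutoff_hz / (eda$fs / 2), type = "low")
  # filter the deviation from the mean: the narrow recursion starts from
  # a zero state, so a large DC offset would otherwise leave a visible
  # start-up transient
  mu <- mean(eda$samples)
  y <- filtfilt_pad(lp, eda$samples - mu, round(3 * eda$fs)) + mu
  keep <- seq.int(1L, length(y), by = factor)
  signal_record(y[keep], fs = fs_out, units = eda$units,
                label = eda$label, t0 = eda$t0)
}

#' Welch sympathetic EDA index
#'
#' Welch PSD of the de-meaned 2 Hz EDA record (Blackman window of
#' `cfg$eda_window_len` samples, 50% overlap); `EDASymp` integrates the
#' density over the sudomotor band 0.045-0.25 Hz, and `EDASympn` divides
#' by the total power over `(0, 1 Hz]` in analogy with the HRV
#' normalization.
#'
#' @param eda2 EDA [signal_record()] at `cfg$eda_fs_spectral` Hz, at least
#'   one window long.
#' @param cfg an [analysis_config()].
#' @return List with `EDASymp` (uS^2) and `EDASympn` (normalized units).
#' @export
edasymp <- function(eda2, cfg = analysis_config()) {
  stopifnot(inherits(eda2, "signal_record"))
  if (abs(eda2$fs - cfg$eda_fs_spectral) > 1e-9)
    stop(sprintf("expected a %g Hz record, got %g Hz",
                 cfg$eda_fs_spectral, eda2$fs), call. = FALSE)
  spec <- welch_psd(eda2, cfg$eda_window_len, cfg$welch_overlap,
                    cfg$welch_window)
  p_band <- band_power(spec, cfg$edasymp_band[1], cfg$edasymp_band[2])
  tot <- total_power(spec)
  if (tot <= 0)
    stop("zero total EDA power: EDASympn undefined", call. = FALSE)
  list(EDASymp = p_band, EDASympn = p_band / tot)
}

#' Variable frequency complex demodulation
#'
#' Two-stage time-frequency decomposition of a low-rate record into
#' band-limited components with instantaneous amplitude, phase, and
#' center-frequency trajectories.
#'
#' Stage 1 (fixed-frequency complex demodulation): `(0, fs/2]` is
#' partitioned into contiguous bands of width `band_width` with centers
#' `f_i = (i - 1/2) * band_width`; the de-meaned signal is demodulated by
#' `exp(-1i 2 pi f_i t)` and low-pass filtered at half the band width
#' (window-method FIR, zero-phase, mirror padding), giving a complex
#' baseband series `z_i` per band.
#'
#' Stage 2 (variable-frequency refinement): each band's dominant
#' instantaneous frequency is estimated from the smoothed derivative of
#' the stage-1 phase (clamped to the band), and the stage-1 component is
#' re-demodulated along that trajectory and filtered with a narrower
#' low-pass.  Refining the band-limited component rather than the raw
#' signal preserves the filter bank's partition of unity: a tone on a
#' band edge is recovered at half amplitude by each neighbour instead of
#' at full amplitude by both.
#'
#' @param x [signal_record()] at a low rate (2 Hz for EDA); de-meaned
#'   internally; at least 120 samples.
#' @param band_width band width Fw in Hz (default 0.08).
#' @param refine_factor stage-2 cutoff as a fraction of the stage-1
#'   cutoff (default 0.75).
#' @param smooth_s span of the trajectory smoother in seconds (default
#'   half the filter length).
#' @return A `"vfcdm_decomposition"`: list with `components` (one per
#'   band: `center_freq_hz` scalar band center, `freq_trajectory_hz`,
#'   `inst_amplitude`, `inst_phase`, `reconstruction`), `fs`,
#'   `band_width`, `filter_len` (samples), and `edge_len` (transient
#'   samples at each end).
#' @export
vfcdm_decompose <- function(x, band_width = 0.08, refine_factor = 0.75,
                            smooth_s = NULL) {
  stopifnot(inherits(x, "signal_record"))
  fs <- x$fs
  n <- length(x$samples)
  if (n < 120)
    stop("VFCDM needs at least 120 samples", call. = FALSE)
  xs <- x$samples - mean(x$samples)
  tt <- (seq_len(n) - 1) / fs

  # window-method FIR length: a third of the record, capped at 6 / Fw s
  L <- min(floor(n / 3), round(6 / band_width * fs))
  if (L %% 2 == 0) L <- L - 1
  if (L < 9) stop("record too short for the demodulation filters",
                  call. = FALSE)
  cut1 <- band_width / 2
  b1 <- fir_lowpass(L, cut1, fs)
  b2 <- fir_lowpass(L, cut1 * refine_factor, fs)
  if (is.null(smooth_s)) smooth_s <- (L / fs) / 2
  sm <- max(1L, as.integer(round(smooth_s * fs)))

  centers <- seq(band_width / 2, fs / 2 - band_width / 2 + 1e-12,
                 by = band_width)
  comps <- lapply(centers, function(fc) {
    z1 <- fir_apply(b1, xs * exp(-2i * pi * fc * tt))
    # dominant instantaneous frequency from the smoothed phase derivative
    ph1 <- unwrap_phase(z1)
    dph <- c(diff(ph1), 0) * fs / (2 * pi)
    dph[n] <- dph[n - 1]
    f_inst <- fc + moving_mean(dph, sm)
    f_inst <- pmin(pmax(f_inst, fc - band_width / 2), fc + band_width / 2)
    # re-demodulate the band-limited component along the trajectory
    phi <- 2 * pi * cumsum(f_inst) / fs
    phi <- phi - phi[1]
    z2 <- fir_apply(b2, z1 * exp(2i * pi * fc * tt) * exp(-1i * phi))
    recon <- 2 * Re(z2 * exp(1i * phi))
    list(center_freq_hz = fc,
         freq_trajectory_hz = f_inst,
         inst_amplitude = 2 * Mod(z2),
         inst_phase = Arg(z2) + (phi %% (2 * pi)),
         reconstruction = recon)
  })
  structure(list(components = comps, fs = fs, band_width = band_width,
                 filter_len = L, edge_len = L, n = n),
            class = "vfcdm_decomposition")
}

#' @export
print.vfcdm_decomposition <- function(x, ...) {
  cat(sprintf(
    "<vfcdm_decomposition> %d bands of %g Hz @ %g Hz, filter %d taps\n",
    length(x$components), x$band_width, x$fs, x$filter_len))
  invisible(x)
}

#' Sum of VFCDM component reconstructions over a frequency range
#'
#' @param dec a `"vfcdm_decomposition"`.
#' @param lo,hi frequency range in Hz; components whose band
#'   `[center - Fw/2, center + Fw/2]` lies within `[lo, hi]` (to a small
#'   tolerance) are summed.
#' @return Numeric vector: summed reconstruction.
#' @export
vfcdm_band_sum <- function(dec, lo, hi) {
  stopifnot(inherits(dec, "vfcdm_decomposition"))
  half <- dec$band_width / 2
  tol <- 1e-9
  sel <- vapply(dec$components, function(cp) {
    cp$center_freq_hz - half >= lo - tol && cp$center_freq_hz + half <= hi + tol
  }, logical(1))
  if (!any(sel)) stop(sprintf("no VFCDM band lies within [%g, %g] Hz",
                              lo, hi), call. = FALSE)
  Reduce(`+`, lapply(dec$components[sel], `[[`, "reconstruction"))
}

#' Time-varying sympathetic EDA index
#'
#' The record is normalized to zero mean and unit variance, decomposed by
#' VFCDM, and the components whose bands lie within the sudomotor range
#' 0.08-0.24 Hz (bands 2 and 3 under the 0.08 Hz partition) are summed.
#' TVSymp is the time average of the instantaneous amplitude (analytic
#' signal magnitude) of that sum, taken over the central region of the
#' record with one filter length excluded at each end to avoid filter
#' transients.  The unit-variance normalization makes the index invariant
#' to affine rescaling of the raw EDA.
#'
#' @param x EDA [signal_record()] at `cfg$eda_fs_spectral` Hz, 120 s by
#'   convention.
#' @param cfg an [analysis_config()]; fields `tvsymp_band`,
#'   `vfcdm_band_width`, `eda_fs_spectral`.
#' @return TVSymp in normalized units (non-negative scalar).
#' @export
tvsymp <- function(x, cfg = analysis_config()) {
  stopifnot(inherits(x, "signal_record"))
  if (abs(x$fs - cfg$eda_fs_spectral) > 1e-9)
    stop(sprintf("expected a %g Hz record, got %g Hz",
                 cfg$eda_fs_spectral, x$fs), call. = FALSE)
  s <- stats::sd(x$samples)
  if (s <= 0)
    stop("zero-variance EDA record: TVSymp undefined", call. = FALSE)
  xn <- signal_record((x$samples - mean(x$samples)) / s, fs = x$fs,
                      units = "n.u.", label = x$label, t0 = x$t0)
  dec <- vfcdm_decompose(xn, band_width = cfg$vfcdm_band_width)
  comp_sum <- vfcdm_band_sum(dec, cfg$tvsymp_band[1], cfg$tvsymp_band[2])
  amp <- Mod(analytic_signal(comp_sum))
  n <- length(amp)
  keep <- seq.int(dec$edge_len + 1L, n - dec$edge_len)
  if (length(keep) < 8)
    stop("record too short to exclude filter transients", call. = FALSE)
  mean(amp[keep])
}
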