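# Internal DSP helpers shared by the ECG and EDA stages.

# Taper of the requested kind; length n.
taper_window <- function(n, kind = c("blackman", "hamming", "hann",
                                     "rectangular")) {
  kind <- match.arg(kind)
  switch(kind,
    blackman = signal::blackman(n),
    hamming = signal::hamming(n),
    hann = signal::hanning(n),
    rectangular = rep(1, n)
  )
}

# Analytic signal via the frequency-domain Hilbert construction.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Zero-phase application of a symmetric odd-length FIR filter with mirror
# padding at both ends (works for complex-valued x).
fir_apply <- function(b, x) {
  L <- length(b)
  stopifnot(L %% 2 == 1)
  n <- length(x)
  pad <- min(L, n - 1)
  left <- x[seq(pad + 1, 2)]
  right <- x[seq(n - 1, n - pad)]
  xp <- c(left, x, right)
  m <- length(xp)
  # linear convolution via FFT, cropped to compensate the (L-1)/2 delay
  nfft <- stats::nextn(m + L - 1, 2)
  Y <- stats::fft(c(xp, rep(0, nfft - m))) *
    stats::fft(c(b, rep(0, nfft - L)))
  y <- stats::fft(Y, inverse = TRUE) / nfft
  if (is.double(x) && !is.complex(x)) y <- Re(y)
  delay <- (L - 1) / 2
  y <- y[(delay + 1):(delay + m)]
  y[(pad + 1):(pad + n)]
}

# Window-method (Hamming) linear-phase low-pass; cutoff in Hz; DC gain
# normalized to exactly 1 (fir1's own scaling targets the passband
# center, which overshoots at DC for very narrow designs).
fir_lowpass <- function(ntaps, cutoff_hz, fs) {
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  w <- cutoff_hz / (fs / 2)
  stopifnot(w > 0, w < 1)
  b <- as.numeric(signal::fir1(ntaps - 1, w, type = "low"))
  b / sum(b)
}

# Centered moving mean with reflective edge padding; width in samples.
moving_mean <- function(x, width) {
  width <- as.integer(width)
  if (width %% 2 == 0) width <- width + 1L
  if (width <= 1L) return(x)
  n <- length(x)
  half <- (width - 1L) %/% 2L
  pad <- min(half, n - 1L)
  xp <- c(x[seq(pad + 1, 2)], x, x[seq(n - 1, n - pad)])
  if (pad < half) { # very short records: extend with edge values
    xp <- c(rep(xp[1], half - pad), xp, rep(xp[length(xp)], half - pad))
  }
  cs <- cumsum(c(0, xp))
  (cs[(width + 1):(width + n)] - cs[1:n]) / width
}

# Single-pass IIR filtering y = filter(b, a, x), via C-level
# stats::filter (convolution for the numerator, recursion for the
# denominator); zero initial conditions.
iir_filt <- function(b, a, x) {
  nb <- length(b)
  if (nb > 1L) {
    xp <- c(rep(0, nb - 1L), x)
    num <- stats::filter(xp, b, method = "convolution", sides = 1)
    num <- as.numeric(num)[nb:(nb - 1L + length(x))]
  } else {
    num <- b * x
  }
  if (length(a) > 1L) {
    as.numeric(stats::filter(num / a[1], -a[-1] / a[1],
                             method = "recursive"))
  } else {
    num / a[1]
  }
}

# Forward-backward IIR filtering (zero phase) with odd-reflection padding
# at both ends to suppress start/end transients.
filtfilt_pad <- function(filt, x, pad) {
  b <- as.numeric(filt$b); a <- as.numeric(filt$a)
  n <- length(x)
  pad <- min(as.integer(pad), n - 1L)
  if (pad >= 1L) {
    left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
    right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
    x <- c(left, x, right)
  }
  y <- iir_filt(b, a, x)
  y <- rev(iir_filt(b, a, rev(y)))
  if (pad >= 1L) y[(pad + 1L):(pad + n)] else y
}

# Zero-phase Butterworth band-pass as a high-pass/low-pass cascade (the
# cascade keeps the recursion numerically stable when the lower edge is a
# tiny fraction of the Nyquist frequency).  Padding scales with the lower
# edge's time constant.
butter_bandpass_zp <- function(x, fs, lo, hi, order_lo = 2, order_hi = 4) {
  nyq <- fs / 2
  stopifnot(lo > 0, hi > lo, hi < nyq)
  # the passband excludes DC; removing the mean up front keeps the
  # zero-state recursion from ringing on a large offset
  x <- x - mean(x)
  pad <- round(min(3, 0.15 / lo + 0.2) * fs)
  if (lo / nyq > 0.02) {
    # both edges comfortably inside (0, 1): one band-pass, two passes
    bp <- signal::butter(min(order_lo, order_hi), c(lo, hi) / nyq,
                         type = "pass")
    return(filtfilt_pad(bp, x, pad))
  }
  hp <- signal::butter(order_lo, lo / nyq, type = "high")
  lp <- signal::butter(order_hi, hi / nyq, type = "low")
  y <- filtfilt_pad(hp, x, pad)
  filtfilt_pad(lp, y, pad)
}

# |H(f)| of a rational filter at frequencies f (Hz), by direct
# evaluation of the transfer polynomials on the unit circle.
filter_gain <- function(filt, f, fs) {
  ev <- function(coef) {
    vapply(f, function(fi) {
      sum(coef * exp(-1i * 2 * pi * fi / fs * (seq_along(coef) - 1)))
    }, complex(1))
  }
  Mod(ev(as.numeric(filt$b)) / ev(as.numeric(filt$a)))
}

# |H(f)|^2 of the zero-phase filtering above, for frequency-response
# oracles; mirrors its design branching.
butter_bandpass_zp_gain <- function(fs, lo, hi, f, order_lo = 2, order_hi = 4) {
  nyq <- fs / 2
  if (lo / nyq > 0.02) {
    bp <- signal::butter(min(order_lo, order_hi), c(lo, hi) / nyq,
                         type = "pass")
    return(filter_gain(bp, f, fs)^2)
  }
  hp <- signal::butter(order_lo, lo / nyq, type = "high")
  lp <- signal::butter(order_hi, hi / nyq, type = "low")
  (filter_gain(hp, f, fs) * filter_gain(lp, f, fs))^2
}

# Phase unwrap of a complex series' argument.
unwrap_phase <- function(z) signal::unwrap(Arg(z))

# Trailing running maximum over a window of w samples (max over
# [i - w + 1, i], truncated at the start), via the two-pass block-cummax
# algorithm so the cost is O(n) rather than O(n * w).
run_max_trailing <- function(x, w) {
  n <- length(x)
  w <- as.integer(w)
  if (w <= 1L) return(x)
  m <- ceiling(n / w)
  xp <- c(x, rep(-Inf, m * w - n))
  M <- matrix(xp, nrow = w)
  L <- as.vector(apply(M, 2, cummax))                   # block start .. i
  R <- as.vector(apply(M[w:1, , drop = FALSE], 2, cummax)[w:1, , drop = FALSE]) # i .. block end
  i <- seq_len(n)
  j <- i - w + 1L
  out <- numeric(n)
  head <- j < 1L
  out[head] <- cummax(x)[i[head]]
  out[!head] <- pmax(R[j[!head]], L[i[!head]])
  out
}
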