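# Independent oracles used across the suite.  Each one recomputes a
# quantity from first principles, without calling the package's own
# implementation path.

# Brute-force Welch estimate: explicitly slice, de-mean, taper, transform
# and average the segments, with textbook one-sided density scaling.
oracle_welch <- function(x, fs, m, overlap = 0.5, taper = NULL) {
  if (is.null(taper)) {
    k <- 0:(m - 1)
    taper <- 0.42 - 0.5 * cos(2 * pi * k / (m - 1)) +
      0.08 * cos(4 * pi * k / (m - 1))
  }
  step <- round(m * (1 - overlap))
  starts <- seq(1, length(x) - m + 1, by = step)
  acc <- numeric(m %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + m - 1)]
    seg <- (seg - mean(seg)) * taper
    P <- Mod(stats::fft(seg))^2 / (fs * sum(taper^2))
    one <- P[1:(m %/% 2 + 1)]
    if (m %% 2 == 0) one[2:(m %/% 2)] <- 2 * one[2:(m %/% 2)]
    else one[2:(m %/% 2 + 1)] <- 2 * one[2:(m %/% 2 + 1)]
    acc <- acc + one
  }
  list(freqs = (0:(m %/% 2)) * fs / m, density = acc / length(starts))
}

# Closed-form Friedman statistic for a tie-free table.
oracle_friedman_stat <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  Rj <- colSums(r)
  12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
}

# Exact permutation p-value by full enumeration of within-row orderings.
oracle_friedman_exact_p <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  obs <- oracle_friedman_stat(m)
  perm_list <- all_perms(k)
  choices <- rep(list(seq_along(perm_list)), n)
  grid <- do.call(expand.grid, choices)
  hits <- 0
  for (g in seq_len(nrow(grid))) {
    mm <- t(vapply(seq_len(n), function(i) {
      r[i, ][perm_list[[as.integer(grid[g, i])]]]
    }, numeric(k)))
    Rj <- colSums(mm)
    Q <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
    if (Q >= obs - 1e-12) hits <- hits + 1
  }
  hits / nrow(grid)
}

all_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1)) {
    for (pos in 0:(k - 1)) out[[length(out) + 1]] <- append(p, k, after = pos)
  }
  out
}

# Magnitude response of an N-point moving average at frequency f (Hz).
oracle_moving_mean_gain <- function(f, n_taps, fs) {
  w <- pi * f / fs
  abs(sin(n_taps * w) / (n_taps * sin(w)))
}

# Detection performance of a beat detector against ground-truth times.
match_beats <- function(detected, truth, tol_s = 0.05) {
  tp <- sum(vapply(truth, function(tb) any(abs(detected - tb) <= tol_s),
                   logical(1)))
  fp <- sum(vapply(detected, function(d) all(abs(truth - d) > tol_s),
                   logical(1)))
  err <- vapply(truth, function(tb) {
    m <- min(abs(detected - tb)); if (is.finite(m)) m else NA_real_
  }, numeric(1))
  list(sensitivity = tp / length(truth),
       ppv = if (length(detected)) tp / length(detected) else NA_real_,
       max_err_s = max(err))
}
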