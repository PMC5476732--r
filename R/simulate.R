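# Synthetic cohort generator.  Emulates the study's recording conditions
# (120 s EDA + 240 s ECG at 400 Hz per run, 13 runs every other hour,
# 10 subjects, 5-min go/no-go task logs) with ground truth exposed for
# every quantity the pipeline estimates.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Bi-exponential (Bateman) SCR kernel, peak-normalized to 1.
bateman_kernel <- function(t, rise_s = 0.75, decay_s = 4) {
  k <- exp(-t / decay_s) - exp(-t / rise_s)
  k[t < 0] <- 0
  t_peak <- log(decay_s / rise_s) * rise_s * decay_s / (decay_s - rise_s)
  k / (exp(-t_peak / decay_s) - exp(-t_peak / rise_s))
}

#' Generate a synthetic EDA record
#'
#' EDA = tonic + phasic + measurement noise.  The tonic component starts
#' at zero (the recording device is re-zeroed at the start of every run)
#' and drifts slowly by at most `drift_max` uS over the record.  The
#' phasic component is a train of Bateman-kernel SCRs (0.75 s rise, 4 s
#' decay) with Poisson onsets at `arousal * scr_rate_base` events/min and
#' log-normal amplitudes around `amp_median` uS.  White measurement noise
#' has sd `noise_sd` uS.  Fully deterministic given `seed`.
#'
#' @param arousal non-negative arousal scalar multiplying the SCR rate.
#' @param duration_s record length in seconds (>= 120).
#' @param fs sampling rate in Hz (default 400).
#' @param seed integer RNG seed.
#' @param scr_rate_base SCR rate at arousal 1, events/min (default 4).
#' @param amp_median median SCR amplitude, uS (default 0.3).
#' @param amp_sdlog log-sd of SCR amplitudes (default 0.35).
#' @param rise_s,decay_s Bateman kernel time constants, s (0.75, 4).
#' @param drift_max maximum tonic drift over the run, uS (default 0.5).
#' @param noise_sd measurement noise sd, uS (default 0.005).
#' @param onset_times optional explicit SCR onset times (seconds),
#'   overriding the Poisson draw -- used to implant a known event train.
#' @param amplitudes optional explicit amplitudes paired with
#'   `onset_times`.
#' @return List with `record` (a [signal_record()], uS) and `truth`
#'   (list: `scr_onsets`, `scr_amplitudes`, `tonic`, `arousal`).
#' @export
generate_eda <- function(arousal, duration_s = 120, fs = 400, seed = 1,
                         scr_rate_base = 4, amp_median = 0.3,
                         amp_sdlog = 0.35, rise_s = 0.75, decay_s = 4,
                         drift_max = 0.5, noise_sd = 0.005,
                         onset_times = NULL, amplitudes = NULL) {
  if (arousal < 0) stop("arousal must be >= 0", call. = FALSE)
  if (duration_s < 120) stop("duration must be >= 120 s", call. = FALSE)
  n <- as.integer(round(duration_s * fs))
  tt <- (0:(n - 1)) / fs
  with_seed(seed, {
    slope <- stats::runif(1, 0.2, 1) * drift_max
    tonic <- slope * tt / duration_s +
      0.05 * sin(2 * pi * 0.004 * tt + stats::runif(1, 0, 2 * pi))
    tonic <- tonic - tonic[1]  # device re-zeroed at run start

    if (is.null(onset_times)) {
      rate_per_s <- arousal * scr_rate_base / 60
      n_ev <- stats::rpois(1, rate_per_s * duration_s)
      onset_times <- sort(stats::runif(n_ev, 0, duration_s - 5))
    } else {
      onset_times <- sort(as.numeric(onset_times))
    }
    if (is.null(amplitudes)) {
      amplitudes <- stats::rlnorm(length(onset_times),
                                  log(amp_median), amp_sdlog)
    }
    stopifnot(length(amplitudes) == length(onset_times))

    phasic <- numeric(n)
    horizon <- as.integer(round(min(30, duration_s) * fs))
    for (i in seq_along(onset_times)) {
      i0 <- as.integer(floor(onset_times[i] * fs)) + 1L
      i1 <- min(n, i0 + horizon)
      if (i0 > n) next
      tau <- (seq.int(i0, i1) - 1) / fs - onset_times[i]
      phasic[i0:i1] <- phasic[i0:i1] +
        amplitudes[i] * bateman_kernel(tau, rise_s, decay_s)
    }
    noise <- stats::rnorm(n, 0, noise_sd)
    list(
      record = signal_record(tonic + phasic + noise, fs = fs, units = "uS",
                             label = "eda"),
      truth = list(scr_onsets = onset_times, scr_amplitudes = amplitudes,
                   tonic = tonic, arousal = arousal)
    )
  })
}

# Stereotyped P-QRS-T beat template evaluated at offsets tau (s) from the
# R apex; amplitudes in mV.
ecg_template <- function(tau) {
  0.15 * exp(-(tau + 0.20)^2 / (2 * 0.025^2)) -  # P
  0.10 * exp(-(tau + 0.035)^2 / (2 * 0.010^2)) + # Q
  1.00 * exp(-tau^2 / (2 * 0.012^2)) -           # R
  0.15 * exp(-(tau - 0.035)^2 / (2 * 0.010^2)) + # S
  0.30 * exp(-(tau - 0.25)^2 / (2 * 0.050^2))    # T
}

#' Generate a synthetic ECG record
#'
#' Beats are placed on an RR series with sinusoidal low-frequency (0.1 Hz)
#' and high-frequency (0.25 Hz) modulation plus white jitter:
#' `RR_n = 60000 / hr + lf_amp sin(2 pi 0.1 t_n) + hf_amp sin(2 pi 0.25 t_n)
#' + N(0, jitter_ms)` (ms).  A stereotyped P-QRS-T template is placed at
#' each cumulative beat time and white noise is added at `snr_db` relative
#' to the clean waveform.  Fully deterministic given `seed`.
#'
#' @param mean_hr_bpm mean heart rate, 40-180 bpm.
#' @param lf_amp_ms,hf_amp_ms modulation amplitudes in ms.
#' @param duration_s record length, s (default 240).
#' @param fs sampling rate, Hz (default 400).
#' @param seed integer RNG seed.
#' @param jitter_ms white RR jitter sd, ms (default 5).
#' @param snr_db waveform signal-to-noise ratio, dB (default 25).
#' @param f_lf,f_hf modulation frequencies, Hz (0.1, 0.25).
#' @return List with `record` (a [signal_record()], mV) and `truth`
#'   (list: `beat_times_s`, `rr_ms`).
#' @export
generate_ecg <- function(mean_hr_bpm, lf_amp_ms = 0, hf_amp_ms = 0,
                         duration_s = 240, fs = 400, seed = 1,
                         jitter_ms = 5, snr_db = 25,
                         f_lf = 0.1, f_hf = 0.25) {
  if (mean_hr_bpm < 40 || mean_hr_bpm > 180)
    stop("mean heart rate must be in [40, 180] bpm", call. = FALSE)
  rr0 <- 60000 / mean_hr_bpm
  if (rr0 - lf_amp_ms - hf_amp_ms <= 250)
    stop("modulation amplitudes drive RR below 250 ms", call. = FALSE)
  with_seed(seed, {
    t_beat <- 0.5
    beats <- numeric(0)
    while (t_beat < duration_s - 0.5) {
      beats <- c(beats, t_beat)
      rr <- rr0 + lf_amp_ms * sin(2 * pi * f_lf * t_beat) +
        hf_amp_ms * sin(2 * pi * f_hf * t_beat) +
        stats::rnorm(1, 0, jitter_ms)
      if (rr <= 250)
        stop("RR interval fell below 250 ms", call. = FALSE)
      t_beat <- t_beat + rr / 1000
    }
    n <- as.integer(round(duration_s * fs))
    x <- numeric(n)
    half_w <- as.integer(round(0.35 * fs))
    for (tb in beats) {
      c0 <- as.integer(round(tb * fs)) + 1L
      i0 <- max(1L, c0 - half_w)
      i1 <- min(n, c0 + half_w)
      tau <- (seq.int(i0, i1) - 1) / fs - tb
      x[i0:i1] <- x[i0:i1] + ecg_template(tau)
    }
    noise_sd <- sqrt(mean(x^2)) / 10^(snr_db / 20)
    x <- x + stats::rnorm(n, 0, noise_sd)
    list(record = signal_record(x, fs = fs, units = "mV", label = "ecg"),
         truth = list(beat_times_s = beats, rr_ms = diff(beats) * 1000))
  })
}

#' Subject profile for the behavioural simulator
#'
#' @param baseline_scl baseline tonic level, uS (kept for completeness;
#'   the recording device re-zeroes every run).
#' @param scr_rate_base SCR rate at arousal 1, events/min.
#' @param rt_base asymptotic mean Go reaction time, ms.
#' @param learning_gain fractional RT elevation on run 1 that decays over
#'   the learning runs.
#' @param fatigue_onset_run first run of the fatigue decline.
#' @param fatigue_slope per-run fractional RT increase after onset.
#' @param acc_stroop,acc_repeat plateau no-go withhold probabilities.
#' @param acc_decline per-run drop in the withhold log-odds after onset.
#' @param seed integer seed associated with the subject.
#' @return A `"subject_profile"` list.
#' @export
subject_profile <- function(baseline_scl = 2, scr_rate_base = 4,
                            rt_base = 450, learning_gain = 0.12,
                            fatigue_onset_run = 9, fatigue_slope = 0.04,
                            acc_stroop = 0.85, acc_repeat = 0.9,
                            acc_decline = 0.45, seed = 1) {
  stopifnot(baseline_scl > 0, scr_rate_base > 0, rt_base > 0,
            fatigue_onset_run >= 1, fatigue_onset_run <= 13)
  structure(list(baseline_scl = baseline_scl,
                 scr_rate_base = scr_rate_base, rt_base = rt_base,
                 learning_gain = learning_gain,
                 fatigue_onset_run = fatigue_onset_run,
                 fatigue_slope = fatigue_slope,
                 acc_stroop = acc_stroop, acc_repeat = acc_repeat,
                 acc_decline = acc_decline, seed = seed),
            class = "subject_profile")
}

# Multiplicative RT factor for learning (elevated early runs) and
# fatigue (rising after onset).
rt_run_factor <- function(profile, run) {
  learn <- if (run == 1) 1 + profile$learning_gain
           else if (run == 2) 1 + profile$learning_gain / 2
           else 1
  fat <- if (run >= profile$fatigue_onset_run)
    1 + profile$fatigue_slope * (run - profile$fatigue_onset_run + 1)
  else 1
  learn * fat
}

# Withhold probability for a no-go kind on a given run (logistic decline
# after the fatigue onset).
acc_run_prob <- function(profile, run, kind) {
  base <- if (kind == "STROOP_NOGO") profile$acc_stroop else profile$acc_repeat
  drop <- if (run >= profile$fatigue_onset_run)
    profile$acc_decline * (run - profile$fatigue_onset_run + 1)
  else 0
  stats::plogis(stats::qlogis(base) - drop)
}

#' Generate a trial log for one run
#'
#' 200 trials on a 1.5 s pitch (900 ms stimulus + 600 ms inter-stimulus
#' interval over a 5-min run).  Mean Go reaction time follows
#' `rt_base * learning(run) * fatigue(run)` with log-normal trial noise;
#' no-go withhold success declines logistically after the fatigue onset
#' run.  Responses falling past the 1500 ms window are recorded as
#' misses.
#'
#' @param profile a [subject_profile()].
#' @param run run number, 1..13.
#' @param seed integer RNG seed.
#' @param n_trials trials per run (default 200).
#' @param trial_s trial pitch in seconds (default 1.5).
#' @param kind_probs probabilities of GO / STROOP_NOGO / REPEAT_NOGO
#'   (default 0.8, 0.1, 0.1).
#' @return List with `trials` (list of [task_trial()]) and `truth`
#'   (expected `Go_RT`, `Stroop_NoGo_acc`, `Repeat_NoGo_acc`).
#' @export
generate_trials <- function(profile, run, seed = 1, n_trials = 200,
                            trial_s = 1.5,
                            kind_probs = c(0.8, 0.1, 0.1)) {
  stopifnot(inherits(profile, "subject_profile"))
  if (run < 1 || run > 13) stop("run must be in 1..13", call. = FALSE)
  with_seed(seed, {
    kinds <- sample(trial_kinds(), n_trials, replace = TRUE,
                    prob = kind_probs)
    # guarantee at least one of each kind so per-run indices are defined
    for (kk in trial_kinds()) {
      if (!any(kinds == kk)) kinds[sample.int(n_trials, 1)] <- kk
    }
    mu_rt <- profile$rt_base * rt_run_factor(profile, run)
    sdlog <- 0.25
    trials <- vector("list", n_trials)
    for (i in seq_len(n_trials)) {
      onset <- (i - 1) * trial_s
      kind <- kinds[i]
      if (kind == "GO") {
        rt <- stats::rlnorm(1, log(mu_rt) - sdlog^2 / 2, sdlog)
        if (stats::runif(1) < 0.02 || rt > 1500) {
          trials[[i]] <- task_trial(i, kind, onset, FALSE)
        } else {
          trials[[i]] <- task_trial(i, kind, onset, TRUE, rt)
        }
      } else {
        withheld <- stats::runif(1) < acc_run_prob(profile, run, kind)
        if (withheld) {
          trials[[i]] <- task_trial(i, kind, onset, FALSE)
        } else {
          rt <- min(1499, stats::rlnorm(1, log(mu_rt) - sdlog^2 / 2, sdlog))
          trials[[i]] <- task_trial(i, kind, onset, TRUE, rt)
        }
      }
    }
    list(trials = trials,
         truth = list(Go_RT = mu_rt,
                      Stroop_NoGo_acc = acc_run_prob(profile, run,
                                                     "STROOP_NOGO"),
                      Repeat_NoGo_acc = acc_run_prob(profile, run,
                                                     "REPEAT_NOGO")))
  })
}

# Per-run arousal profile: learning elevation on runs 1-2, plateau, then
# decline after run 9 ("paper_shaped", down to 0.4 of plateau by the last
# run), or flat 1 ("null").
arousal_profile <- function(n_runs, effect) {
  runs <- seq_len(n_runs)
  if (effect == "null") return(rep(1, n_runs))
  a <- rep(1, n_runs)
  a[runs == 1] <- 1.15
  a[runs == 2] <- 1.05
  late <- runs > 9
  a[late] <- 1 - 0.6 * (runs[late] - 9) / max(1, n_runs - 9)
  a
}

#' Generate a full synthetic cohort
#'
#' Per-subject profiles are drawn around population means; each
#' subject-run yields an EDA record, an ECG record and a trial log.
#' Under `effect = "paper_shaped"` the per-run arousal follows a
#' learning/plateau/decline shape (runs 1-2 elevated, decline after run
#' 9) driving SCR rate and the sympathetic EDA indices down late in the
#' protocol, while Go reaction time rises and no-go accuracies fall, and
#' the LF modulation of heart rate grows modestly; `effect = "null"`
#' holds every run effect at zero.
#'
#' @param n_subjects number of subjects (>= 2; default 10).
#' @param n_runs number of runs (default 13).
#' @param effect `"paper_shaped"` or `"null"`.
#' @param seed integer RNG seed.
#' @param fs_eda,fs_ecg sampling rates in Hz (default 400, the recording
#'   rate; lower rates are useful for large simulation studies).
#' @param eda_duration_s,ecg_duration_s segment lengths, s (120 and 240).
#' @return List with `sessions` (list of [run_session()], length
#'   `n_subjects * n_runs`) and `truth` (list: `arousal` runs-vector,
#'   `profiles`, per-session ground truths keyed `subject.run`).
#' @export
generate_cohort <- function(n_subjects = 10, n_runs = 13,
                            effect = c("paper_shaped", "null"), seed = 1,
                            fs_eda = 400, fs_ecg = 400,
                            eda_duration_s = 120, ecg_duration_s = 240) {
  effect <- match.arg(effect)
  if (n_subjects < 2) stop("need at least 2 subjects", call. = FALSE)
  arousal <- arousal_profile(n_runs, effect)
  base <- with_seed(seed, {
    list(rt = stats::rnorm(n_subjects, 450, 40),
         rate = pmax(2, stats::rnorm(n_subjects, 4, 0.6)),
         scl = pmax(0.5, stats::rnorm(n_subjects, 2, 0.4)),
         hr = stats::rnorm(n_subjects, 70, 5),
         lf0 = pmax(10, stats::rnorm(n_subjects, 30, 5)),
         hf0 = pmax(10, stats::rnorm(n_subjects, 40, 5)))
  })
  profiles <- lapply(seq_len(n_subjects), function(s) {
    subject_profile(
      baseline_scl = base$scl[s], scr_rate_base = base$rate[s],
      rt_base = base$rt[s],
      learning_gain = if (effect == "null") 0 else 0.12,
      fatigue_onset_run = 9,
      fatigue_slope = if (effect == "null") 0 else 0.04,
      acc_decline = if (effect == "null") 0 else 0.45,
      seed = seed + s)
  })
  sessions <- vector("list", n_subjects * n_runs)
  session_truth <- vector("list", n_subjects * n_runs)
  idx <- 0L
  for (s in seq_len(n_subjects)) {
    for (r in seq_len(n_runs)) {
      idx <- idx + 1L
      sub_seed <- (seed * 7919L + s * 131L + r) %% 2147483647L
      # arousal drives both SCR rate and amplitude: hypoarousal recruits
      # fewer and smaller sudomotor responses, pushing much of the train
      # below the counting threshold late in the protocol
      eda <- generate_eda(arousal[r], duration_s = eda_duration_s,
                          fs = fs_eda, seed = sub_seed,
                          scr_rate_base = base$rate[s],
                          amp_median = 0.3 * arousal[r]^1.5)
      lf_amp <- if (effect == "null") base$lf0[s]
                else base$lf0[s] * (1 + 0.04 * (r - 1))
      ecg <- generate_ecg(base$hr[s], lf_amp_ms = lf_amp,
                          hf_amp_ms = base$hf0[s],
                          duration_s = ecg_duration_s, fs = fs_ecg,
                          seed = sub_seed + 1L)
      trl <- generate_trials(profiles[[s]], r, seed = sub_seed + 2L)
      sid <- sprintf("S%02d", s)
      sessions[[idx]] <- run_session(sid, r, eda$record, ecg$record,
                                     trl$trials)
      session_truth[[idx]] <- list(subject = sid, run = r,
                                   eda = eda$truth, ecg = ecg$truth,
                                   trials = trl$truth)
    }
  }
  names(session_truth) <- vapply(session_truth, function(x)
    paste0(x$subject, ".", x$run), character(1))
  list(sessions = sessions,
       truth = list(arousal = arousal, profiles = profiles,
                    sessions = session_truth, effect = effect))
}
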