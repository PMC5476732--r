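---
title: "Methods: autonomic indices from EDA and HRV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autonomic indices from EDA and HRV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ansindex)
```

## The problem

Electrodermal activity (EDA) is driven exclusively by the sympathetic
branch of the autonomic nervous system, which makes it an attractive
window on arousal. Protocols that probe vigilance — for example repeated
runs of a go/no-go color-word task across a 24-hour sleep-deprivation
session — need scalar per-run indices that can be compared across runs
within subject. This package computes the standard battery:

* **Time domain, EDA** — the skin conductance level (`SCL`, mean tonic
  conductance over a 2-minute window) and the rate of non-specific skin
  conductance responses (`NSSCRs`, events/min above a 0.05 μS rise
  threshold);
* **Frequency domain, EDA** — `EDASymp` (band power of 2 Hz EDA over
  0.045–0.25 Hz, Welch/Blackman) with its normalized form `EDASympn`,
  and `TVSymp`, the time-varying sympathetic index built from the
  0.08–0.24 Hz components of a variable frequency complex demodulation
  (VFCDM) of unit-variance EDA;
* **HRV** — `HRVLF` (0.045–0.15 Hz), `HRVHF` (0.15–0.4 Hz) and their
  total-power-normalized forms, from an RR series obtained by
  envelope-based R-peak detection and 4 Hz cubic-spline resampling;
* **Behaviour** — mean Go reaction time and the two no-go withhold
  accuracies of the error awareness task;
* **Statistics** — a Friedman rank test per index across runs (subjects
  as blocks), Nemenyi-type post-hoc comparisons on average ranks, and
  Pearson correlations between per-run mean profiles.

Because the kind of recordings this pipeline targets are rarely shared,
the package ships a deterministic synthetic-data generator that emulates
the study conditions and exposes ground truth for every quantity the
pipeline estimates, so all validation is parameter-recovery testing.

## Spectral core

`welch_psd()` implements the averaged modified periodogram with an
explicit contract: segments of `window_len` samples start at multiples
of `window_len * (1 - overlap)`; partial trailing segments are dropped;
each segment is de-meaned, tapered (Blackman by default) and transformed
at the window length (no zero padding); the one-sided density is
normalized by the taper power so that `sum(density) * df` estimates the
signal variance. `band_power()` sums `density * df` over bins whose
center satisfies `lo <= f < hi`. Two boundary rules matter:

* the half-open convention means the LF/HF bands sharing the 0.15 Hz
  edge never double-count a bin;
* the DC bin is always excluded, and a band ending exactly at Nyquist
  includes the Nyquist bin, so that bands partitioning `(0, fs/2]` sum
  exactly to the total power.

## ECG to HRV

ECG is band-passed 0.05–40 Hz with zero-phase (forward–backward)
Butterworth filtering. Very low high-pass edges make a direct band-pass
recursion ill-conditioned, so the filter is a high-pass/low-pass
cascade, the input is de-meaned first, and odd-reflection padding
suppresses the start-up transients of the zero-state recursion.

The R-peak delineation function is the magnitude of the analytic signal
of a 5–25 Hz copy of the ECG. Candidate beats are local maxima of this
envelope above an adaptive threshold (half the trailing 2-s envelope
maximum, floored at 0.2 of the global maximum so the warm-up region
before the first beat cannot fire on noise), separated by a 250 ms
refractory period, and refined to the raw-ECG maximum within ±50 ms.
These are conventional QRS-detector values and all of them are
arguments.

Manual ectopic-beat editing is not reproducible, so `clean_rr()`
automates it: intervals outside `[0.66, 1.5]` times a running 5-interval
median are flagged and replaced by interpolation, and a segment with
more than 20% corrections is rejected outright rather than silently
repaired. The corrected RR series is resampled to 4 Hz with an `fmm`
cubic spline (exact for cubic trends, verified in the tests), indexed at
each interval's terminating beat and evaluated from the first beat so a
240-s record yields 960 samples.

## EDA decomposition and SCR counting

Two tonic extractors are provided. The default detrends with a 20 s
centered moving mean (reflective edges), which has unit DC gain and a
first spectral null at 0.05 Hz — slow drift stays tonic, response-shaped
transients stay phasic. The verbatim alternative (`tonic_method =
"fir"`) is a window-method FIR low-pass of order 10 with a 0.0004 Hz
cutoff and DC gain normalized to exactly 1. Eleven taps cannot realize a
0.0004 Hz transition at any practical rate: its magnitude response stays
within a fraction of a percent of unity far beyond the sudomotor band,
so its phasic residual is nearly zero. It is kept because it is the
stated design this pipeline descends from, but the moving-mean extractor
is the one whose SCR recovery is validated; both satisfy the exact
reconstruction identity `tonic + phasic = raw`.

An SCR is a trough-to-peak rise of the (lightly smoothed) phasic signal
of at least 0.05 μS, with three noise guards: reversals smaller than 10%
of the threshold are ignored (hysteresis), rises faster than 0.5 s are
rejected, and onsets within 1 s of the previous onset are suppressed.
Each trough/peak pair is an event of its own, so a response starting on
the falling limb of its predecessor is counted separately — the overlap
rule. Because a centered moving mean dips slightly *ahead* of a large
response, the trough can precede the true rise by seconds; the reported
onset is therefore the point where the rise has covered 10% of its
amplitude, which lands within one second of implanted ground-truth
onsets in the tests. `NSSCRs` counts events per non-overlapping 60-s
minute and averages the minutes.

## VFCDM and TVSymp

EDA is anti-alias filtered and decimated to 2 Hz. Stage 1 of the VFCDM
partitions `(0, 1]` Hz into contiguous 0.08 Hz bands centered at
`f_i = (i - 1/2) * 0.08`; the de-meaned signal is demodulated by
`exp(-i 2 pi f_i t)` and low-passed at half the band width with a
window-method FIR (length one third of the record, capped at `6 / Fw`
seconds; zero-phase with mirror padding). Stage 2 estimates each band's
dominant instantaneous frequency from the smoothed stage-1 phase
derivative (clamped to the band) and re-demodulates **the stage-1
component** along that trajectory with a slightly narrower low-pass.

Refining the component rather than the raw signal is a deliberate
choice: re-demodulating the raw signal per band lets a tone sitting on a
band edge be recovered at full amplitude by *both* neighbours, breaking
the filter bank's partition of unity. Component-wise refinement keeps
adjacent-band gains summing to one at the crossover (the two halves of
an edge tone add back to the full amplitude) while still sharpening the
frequency trajectory; the chirp-tracking test (0.09→0.23 Hz tracked
within 0.02 Hz) validates the refinement.

`TVSymp` normalizes the 2 Hz record to zero mean and unit variance, sums
the reconstructions of the components whose bands lie inside
0.08–0.24 Hz (bands 2 and 3), and averages the analytic-signal magnitude
of that sum over the central region, excluding one filter length at each
end where transients live. The unit-variance normalization makes TVSymp
exactly invariant to affine rescaling of the raw EDA; a pure in-band
sinusoid has unit variance after normalization and hence amplitude
`sqrt(2)`, a closed-form anchor the tests check to 5%.

The normalization of `EDASympn` is defined here as band power divided by
total power over `(0, 1]` Hz, by analogy with the HRV normalized units;
whether spectral indices should use raw or phasic EDA is likewise not
settled usage — this implementation uses the de-meaned raw record, and
both choices are arguments.

## Behavioural metrics

Trials are one of GO, STROOP_NOGO (color/word mismatch) or REPEAT_NOGO
(consecutive repetition). `Go_RT` is the mean reaction time over
responded Go trials; each accuracy is the withheld fraction of its no-go
kind. The response window is the 1500 ms trial pitch (900 ms stimulus +
600 ms inter-stimulus interval); later presses count as misses. No
error-awareness (post-error signalling) scoring is attempted — the
indices defined above do not use it.

## Rank statistics

`friedman_test()` ranks within subjects and uses the tie-corrected
statistic

Q = (k−1) · Σ_j (R_j − n(k+1)/2)² / (Σ_ij r_ij² − n·k(k+1)²/4),

referred to χ²(k−1). Ties are rare for continuous indices but routine
for accuracies, hence the correction is always applied. The exact method
computes the full `(k!)^n` within-row permutation distribution by
dynamic programming over column rank-sum states — mathematically
identical to enumeration (verified against brute force on small tables)
but feasible at, say, n = 10 subjects and k = 3 runs. A caveat worth
stating: with k = 3 the χ² reference (df = 2) is coarse for small n —
the permutation distribution is visibly discrete there — and the gap
between exact and asymptotic p-values shrinks only gradually with n
(the test suite checks their mean agreement at n = 15), so exact
p-values are preferable for very small designs.

Post-hoc comparisons use the Nemenyi critical difference on average
ranks, `CD = q_{α,k,∞} / sqrt(2) · sqrt(k(k+1) / (12 n))`, with a
Bonferroni-on-ranks alternative behind `posthoc_method`. α defaults to
0.05.

## The synthetic cohort

`generate_eda()` builds EDA as tonic + phasic + noise: the tonic starts
at zero (the recording amplifier is re-zeroed at every run start) and
drifts by at most 0.5 μS per run with a slow sinusoidal component;
the phasic train has Poisson onsets at `arousal × scr_rate_base`
events/min and Bateman-kernel responses (0.75 s rise, 4 s decay —
conventional SCR modelling constants) with log-normal amplitudes;
measurement noise is white with σ = 0.005 μS. `generate_ecg()` places a
stereotyped P-QRS-T template on an RR series with sinusoidal 0.1 Hz and
0.25 Hz modulation plus 5 ms jitter, at a configurable waveform SNR.
`generate_trials()` emits 200 trials per 5-minute run (80% GO, 10% each
no-go kind) with learning (runs 1–2), plateau, and post-onset fatigue
profiles for reaction time and withhold probability. Everything is
deterministic given a seed, and every generated quantity the pipeline
estimates is returned as ground truth.

`generate_cohort(effect = "paper_shaped")` ties the per-run arousal to a
learning/plateau/decline shape — elevated runs 1–2, plateau at 1.0,
linear decline after run 9 to 0.4 by run 13. Arousal scales both the
SCR rate and the median SCR amplitude (as `arousal^1.5`): hypoarousal
recruits fewer and smaller sudomotor responses, consistent with classic
reports of reduced SCR amplitude after sleep deprivation, and late in
the protocol much of the train falls below the 0.05 μS counting
threshold. These coupling constants — plateau rate 4 events/min under
task load, amplitude exponent 1.5, arousal floor 0.4 — were fixed in one
calibration pass so that the programmed decline is reliably detectable
by the rank analysis at the cohort's own size (10 subjects × 13 runs),
and are not revisited; they are ordinary arguments for users who want
weaker or stronger regimes. Reaction time rises and withhold accuracy
falls after the same onset run; LF rate modulation grows modestly with
time awake.

What the generator does **not** emulate: respiration-coupled HF
dynamics beyond a fixed sinusoid, motion artifacts, electrode pops,
ectopic beats (RR cleaning is exercised with implanted artifacts
instead), circadian modulation of the tonic level across runs (the
re-zeroing removes it by design), and any correlation structure between
EDA and ECG noise. Passing the recovery tests therefore demonstrates
correctness of the estimators under clean, stationary-noise conditions,
not robustness to every artifact class of ambulatory recordings.

## Problem sizes and numerical choices

Single-record validation (R-peak suite, SCR implant suite) runs at the
native 400 Hz. The cohort-level simulation studies (null calibration
and programmed-effect detection, 50 seeds each) generate signals at
32 Hz EDA / 100 Hz ECG; these rates keep every processing step —
anti-alias decimation to 2 Hz, QRS envelope detection, 4 Hz RR
resampling — operating unchanged, far above the bands of interest, and
were chosen so a full simulation study is a coffee-break computation
rather than an overnight one. Segment lengths (120 s EDA, 240 s ECG),
window lengths (256 / 128 samples), and all thresholds are identical at
every rate.

Other numerical choices: all zero-phase filtering uses odd-reflection
padding; the narrow anti-alias and band-pass recursions filter the
de-meaned signal to avoid zero-state transients; VFCDM excludes one
filter length at each record end from the TVSymp average; rank ties get
average ranks everywhere; and Friedman tables with any missing cell are
skipped with a warning rather than imputed, because the protocol this
emulates had no missing-data procedure.

## Run/hour bookkeeping

Runs happen every other hour. The default convention is
`hours_awake = 2 * (run − 1)` (run 1 on arrival); the alternative
`2 * run` is available via `hours_convention` because both readings of
the protocol are defensible and neither is asserted as the true one.

## Limitations

* The SCR detector is tuned for the clean synthetic regime; on real
  recordings with motion artifacts its hysteresis and refractory
  parameters would need re-examination against manual scoring.
* The verbatim 10th-order tonic FIR is retained for fidelity but is not
  a functioning separator; treat `tonic_method = "fir"` as a
  documentation artifact, not an analysis option.
* The VFCDM stage-2 trajectory rule (smoothed phase derivative, clamped,
  component-wise re-demodulation) is one defensible surrogate among
  several; it is validated on tones and chirps, not against a reference
  implementation.
* Friedman p-values at k = 3 should use the exact method (see above);
  the cohort analyses here use k = 13, where the χ² approximation is
  comfortable.
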