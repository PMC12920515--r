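---
title: "Methods: envelope TRFs for clean and vocoded speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: envelope TRFs for clean and vocoded speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question and the model

When speech is spectrally degraded — here by noise vocoding, the standard
acoustic simulation of cochlear-implant hearing — listeners still track
its slow amplitude modulations. The working hypothesis this package is
built to examine is a temporal one: clean speech should drive strong
*early* cortical responses (the N1/P2 range, sensory encoding), while
degraded speech should recruit *late* compensatory processing (a positive
deflection around 400 ms), visible as an enhanced late component of the
temporal response function (TRF).

The TRF is the kernel $w(\tau, c)$ of a linear convolutional model from
the broadband speech envelope $s(t)$ to the EEG $r(t, c)$ at channel $c$:

$$ r(t, c) = \sum_{\tau} w(\tau, c)\, s(t - \tau) + \varepsilon(t, c), $$

with lags $\tau$ spanning $-100..600$ ms. Estimation is ridge regression
on the lag-expanded design $X$:

$$ \hat W = (X^\top X + \lambda\, m\, I)^{-1} X^\top Y, $$

where $m$ is the mean diagonal of the penalized block of $X^\top X$, so
the $\lambda$ grid is invariant to stimulus scale (the mTRF convention),
and the intercept column is unpenalized. $\lambda$ is chosen by
leave-one-out cross-validation across sentence-level responses,
minimizing channel-averaged MSE on held-out items, jointly across the two
conditions (one $\lambda$ for both).

Group-level inference follows the sensor-level recipe: per-subject global
field power (GFP, the spatial standard deviation of the TRF across
channels at each lag, population convention), pointwise two-tailed paired
t-tests between conditions, Benjamini–Hochberg FDR correction across the
whole lag axis (one FDR family per analysis surface: lags for time
courses, channels for topographies), and contiguous runs of significant
lags reported as component windows. Component validity is checked against
a stimulus-shuffling null: TRFs refitted with envelopes deranged relative
to the EEG (no envelope keeps its own response), same pipeline, same
$\lambda$.

## What each module assumes

**Vocoder.** Four logarithmically spaced analysis bands spanning
200–5000 Hz; per band: 4th-order zero-phase Butterworth band-pass,
half-wave rectification, 200 Hz low-pass envelope, Gaussian white-noise
carrier. The carrier is band-limited *before* modulation and the
modulated product is re-filtered three times with the band filter: a
single pass leaves modulation sidebands bleeding ~ -13 dB into adjacent
bands, which would defeat the point of a band vocoder; with confinement
the leakage is below -27 dB and per-band RMS (as seen by the analysis
filter) is preserved to 1%. Envelope preservation is quantified on
modulation-band (15 Hz) smoothed band envelopes — the modulation range
the downstream analysis uses (responses are band-passed 1–15 Hz). At the
full 200 Hz envelope bandwidth, correlations in the narrowest band are
bounded well below 1 by the carrier's own Rayleigh envelope fluctuations
for *any* vocoder with stochastic carriers; this is a property of the
measurement, not a defect of the vocoder.

**Front end.** A linear approximation of an auditory filterbank: 128
log-spaced 4th-order zero-phase band-passes over 90–4000 Hz, half-wave
rectification, 30 Hz smoothing, unweighted band average, polyphase
resampling to 256 Hz, clipped at zero. Cochlear compression is omitted
deliberately: the TRF uses only the band-averaged temporal envelope,
which is dominated by modulation content rather than static
nonlinearity. Exact replication of any particular cochlear-model
front end is not attempted.

**Preprocessing.** Continuous EEG: 1–57 Hz windowed-sinc (Hamming)
linear-phase FIR with compensated delay (~3.3 fs taps per Hz of
transition width), polyphase resampling to 256 Hz, 3 s epochs from
-0.5 s before onset (half-open window, the t = 0 sample belongs to the
epoch). Per-item averages of repetitions are band-passed 1–15 Hz with a
4th-order zero-phase Butterworth — a narrow-transition FIR cannot fit a
768-sample epoch. Baseline normalization uses ONE pooled mean and SD from
all pre-onset samples across items and channels, preserving relative
channel power; it is idempotent and refuses degenerate (constant
baseline) input. The alpha-power control metric is Welch PSD (1 s Hann
segments, 50% overlap) averaged over 8–12 Hz at Pz/POz. The control is
computed on epoch-level data, never on repetition averages: averaging
suppresses background activity ~100-fold, so band power of an averaged
response reflects residual stimulus-driven energy rather than the
subject's alpha state, and `run_pipeline()` therefore skips the control
when only averaged responses exist.

**Statistics.** `paired_t` handles degenerate differences explicitly
(all-zero: t = 0, p = 1; constant nonzero: infinite t flagged, p = 0).
`fdr_bh` delegates to the canonical step-up implementation and is tested
against an independent enumeration. Cluster endpoints are lag-sample
times, never interpolated. N1-type windows use the signed minimum when a
peak summary is requested; P2/P400 the signed maximum.

## The synthetic-data generator

No EEG recordings are distributed with the package, so every claim is
exercised on synthetic data with known ground truth. The generator
emulates the reference experimental design: 50 subjects x 2 conditions x 10 sentences
x 100 repetitions, 64 channels at 256 Hz, 3 s epochs.

* **Kernels.** Three Gaussian lag components per condition — N1
  (negative, 90 ms, 15 ms width), P2 (positive, 160 ms, 25 ms), P400
  (positive, 390 ms, 30 ms) — with smooth fronto-central topographies
  peaking near Cz on an idealized 2-d montage. Natural N1/P2 amplitudes
  are 1.5x vocoded; vocoded P400 is 1.5x natural. Subjects get
  multiplicative amplitude scales (SD 20%) and latency jitter (SD 10 ms),
  shared across conditions (they are subject traits).
* **Envelopes.** Low-pass-filtered (3.5 Hz base, 4th-order zero-phase)
  rectified noise with a dominant syllabic AM drawn per item from
  3–4.5 Hz, a 5% RMS broadband rectified-noise floor standing in for
  syllable transients, zero before onset. Item durations are drawn from
  60–100% of 2.5 s. Three of these choices matter and were made for
  stated reasons: (i) the base cutoff and AM ceiling keep stimulus-driven
  response power below the 8–12 Hz alpha band, so the generator injects
  no condition-dependent alpha; (ii) the broadband floor keeps the lagged
  design numerically identifiable (a strictly band-limited envelope makes
  high-frequency kernel structure unrecoverable at any noise level);
  (iii) varying durations and tempi prevent all z-scored envelopes from
  sharing one onset/offset step, which would let the shuffled-pairing
  null capture most of the onset response.
* **Noise.** 1/f (exponent 1, verified by spectral-slope fit) noise,
  spatially correlated through a smooth random mixing matrix with
  unit-variance rows. The noise scale is set per subject from the
  *across-condition mean* post-onset signal power at the configured
  per-epoch SNR: background EEG must not depend on stimulus condition
  (scaling per condition would leak kernel-amplitude differences into
  every band, including alpha). `return = "averaged"` draws the per-item
  average directly with noise SD divided by sqrt(n_reps) — exactly the
  distribution of the mean of Gaussian-noise repetitions.

What the generator does **not** emulate: real head geometry and volume
conduction (topographies are idealized Gaussians), non-Gaussian and
nonstationary EEG artifacts, overlapping responses from preceding
stimuli, cochlear compression, and any true semantic process behind the
late component — the P400 here is a planted kernel, so passing tests
show the *pipeline* recovers and validates such structure, not that the
brain produces it.

## Numerical choices

* Lag indices are `floor(t_min fs) .. ceil(t_max fs)` (181 lags at
  256 Hz); designs are zero-padded outside the epoch so folds have equal
  length.
* Envelope and response are z-scored per item before fitting; constants
  are stored in the model. At `zscore = FALSE` and lambda = 0, a
  noiseless simulated subject is recovered to ~1e-10 relative error.
* The ridge solve is Cholesky-based; a rank-deficient system at
  lambda = 0 raises an error advising lambda > 0.
* Lambda selection takes the **largest** grid value within 1% relative
  of the minimum cross-validated MSE. With heavily averaged responses
  the held-out noise floor is so low that the CV curve is flat over many
  decades; among prediction-equivalent models the most regularized one
  is returned (a one-standard-error-style rule). The plain argmin is
  recovered with `tol = 0`.
* Derangements are drawn by rejection from uniform permutations, which
  is exactly uniform over derangements; with two items the swap is the
  only option.
* Pearson correlations of constant signals are reported as `NA`, never
  coerced to zero, and dropped from channel averages.

## Test and acceptance problem sizes

The test suite regenerates everything from code; sizes were chosen so
the full suite exercises the design-defining counts while remaining
desk-scale, and are part of the package's own test design: ridge-oracle
and exact-recovery checks at the full 256 Hz/64-channel geometry;
group-level kernel recovery with all 50 subjects at 256 Hz; lambda-SNR
monotonicity over 20 paired runs at 64 Hz/16 channels; null calibration
over 200 identical-condition datasets of 50 subjects at 32 Hz/8 channels
(a reduced lag grid); the headline early-natural/late-vocoded contrast
over 20 runs of 50 subjects at 64 Hz/16 channels; permutation validation
at 128 Hz/16 channels for the coupled arm (the 80–103 ms window needs
several lag samples) and 200 pure-noise datasets of 20 subjects at 32 Hz
for the decoupled null; the alpha-control null over 200 runs of 15
subjects. Calibration asserts on null rejection rates allow the binomial
sampling slack of a 200-run estimate, since an exactly calibrated test
rejects at precisely the nominal rate.

## Known limitations

* The vocoder's "synthesize sequentially" step is interpreted as
  band-by-band summation; order of modulation and filtering follows
  standard vocoder practice rather than any specific reference
  implementation.
* The front end is linear; absolute envelope units are arbitrary (only
  scale-equivariance is guaranteed).
* Continuous-recording import (BDF/EDF) and HDF5 containers are out of
  scope here; epoched arrays and plain CSV/JSON artifacts are the
  interchange formats.
* Cluster endpoints are quantized to the lag grid, so reported windows
  coarsen as the sampling rate drops.
* The leave-one-out unit is the sentence-averaged response (10 folds),
  not the single repetition; with 100 repetitions per sentence the
  averaged response is the natural epoch for cross-validation, but
  other splits are not implemented.
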