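---
title: "Models and methods behind aafkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aafkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`aafkit` implements an end-to-end analysis of multi-unit recordings from
the rat anterior auditory field (AAF) in a nested cohort design: recording
sites nested in animals nested in experimental groups (saline-exposed
controls, prenatally VPA-exposed animals, and VPA-exposed animals that
received speech-paired vagus nerve stimulation). Because no public
recordings exist for this design, the package ships a first-class
synthetic-data generator with the statistical structure the analysis
assumes, so that every estimator can be validated by parameter recovery.
This vignette documents the models, the defaults, and the design decisions
that were genuinely open.

## Stimulus set

* **Tone pips** — 25 ms pips on a frequency × level grid spanning 1–32 kHz
  and 0–75 dB SPL. The grid density is not a protocol constant; the package
  default is 81 log-spaced frequencies × 5 dB steps (standard fine-grained
  receptive-field mapping practice), and every analysis accepts coarser
  grids. The analyses and tests in this package use a 21 × 16 grid
  (0.25-octave frequency spacing), which keeps simulation studies fast
  while still resolving characteristic frequency to a quarter octave.
* **Noise-burst trains** — six 25 ms bursts at 7.5, 10, 12.5 or 15 Hz;
  burst k starts at (k−1)·1000/rate ms.
* **Speech tokens** — seven consonant–vowel–consonant tokens ("dad",
  "bad", "gad", "tad", "sad", "rad", "lad"). Vocoded natural recordings are
  out of scope; `synth_speech_proxy()` builds synthetic proxies with a
  label-specific onset signature (band-limited noise bursts for stops and
  frication, tonal glides for approximants) followed by a shared
  formant-like vowel. Any waveform set with distinct label-conditional
  onsets satisfies the analysis contract; the proxies are fixtures.
* **Level convention** — dB SPL is modeled as `94 + 20*log10(rms*sqrt(2))`
  so that a full-scale sine measures 94 dB. Absolute SPL in software is a
  bookkeeping convention (there is no microphone); only relative levels
  matter. Calibration scales a waveform so the loudest 100 ms sliding
  window (one-sample hop, exact) sits at 60 dB SPL.
* **VNS pairing schedules** — pairing events are separated by intertrial
  intervals drawn from an exponential distribution truncated to
  [10 s, 90 s]. Truncation changes the mean, so the exponential rate is
  recalibrated numerically so that the *truncated* mean equals the
  requested 30 s; a 2.5 h session then averages 300 pairing events. The
  protocol text does not say whether the 30 s average counts silence catch
  trials; the package defaults to pairing events only and exposes
  `iti_scope = "all"` for the joint reading. VNS onset leads sound onset by
  50 ms on every pairing event.

## Spike simulation

Responses are inhomogeneous Poisson processes: a homogeneous spontaneous
process (default 5 Hz, a fixture — the source design reports no magnitude)
superposed with evoked "bumps" shaped like the alpha function
(t/τ)·e^(1−t/τ), τ = 5 ms. Because the normalized alpha kernel is exactly a
Gamma(shape 2, scale τ) density, each bump is sampled *exactly* by drawing
a Poisson count and Gamma-distributed spike times. This superposition
construction replaces the more common thinning loop: it is equally exact
for this rate family and fully vectorized, which is what makes the
parameter-recovery suites (hundreds of sites × hundreds of grid cells × 20
trials) affordable. Multi-unit activity is represented by the pooled rate
(a sum of independent Poisson unit processes is itself Poisson, so separate
per-unit simulation would change nothing but the bookkeeping).

Evoked amplitude for a tone is
`base_evoked × gain × tuning × level-drive`, with Gaussian tuning in
log2-frequency around the site's characteristic frequency and a saturating
level function `tanh((L − threshold + 5)/15)` that is exactly zero below
threshold (a hinge, so that "threshold" is a recoverable parameter rather
than the midpoint of a soft sigmoid). Train responses place one bump per
burst with amplitude `gain × adaptation^(k−1)`, times an extra suppression
factor on bursts 3 and 5; the generating-process paired-pulse ratio
therefore equals the adaptation factor. Speech responses place a
label-specific two-bump onset signature inside the 1–40 ms consonant
window plus a sustained vowel component; a `separability` dial scales
label-to-label pattern differences (0 collapses all labels onto one
distribution, which is the classifier's chance-level control).

**Group effect structure.** A `group_effect_config` carries evoked gain,
onset latency shift, per-burst adaptation, odd-burst suppression, phase
jitter, spontaneous rate, and the between-animal / between-site SDs of
log-gain (site log-gain = group mean + animal effect + site effect, i.e. a
nested lognormal). The three shipped presets encode the qualitative
direction of the study's findings and are documented as fixtures, not
estimates: VPA-like = lower gain (0.4×), +2.5 ms onset latency, weaker
within-train adaptation (0.85 vs 0.50, hence a higher paired-pulse ratio),
suppression (0.6×) of steady-state bursts 3 and 5, and larger phase jitter
(12 ms vs 4 ms — set so that phase locking degrades detectably at the fast
train rates, as reported); VNS-like = partial restoration (gain 0.7×,
+0.5 ms latency, adaptation 0.55, no odd-burst suppression, 6 ms jitter).
Latency magnitudes follow the control-group onset scale (14.4 ms mean
baseline latency).

## Receptive-field extraction

The frequency response area (FRA) holds, per grid cell, the mean spikes
per trial in the evoked window (default 5–40 ms, covering the 10–15 ms AAF
onset regime) minus the spontaneous expectation for an equal window; the
spontaneous rate comes from the 100 ms pre-stimulus window pooled over all
trials. The source design states no significance criterion, so the package
defines one and flags it as an assumption: after 3×3 median smoothing
(replicate-padded borders), a cell is significant when its driven count
exceeds 2 standard errors of the spontaneous-equivalent count. Threshold is
the lowest level with any significant cell; CF is the significant frequency
at that level, ties broken toward the (driven-count-weighted) centroid of
the significant region. Under a spontaneous-only null, fewer than 5% of
sites pass the criterion (isolated cells do not survive the median filter).

Bandwidths at threshold + 10…40 dB are octave widths of the contiguous
significant span containing the CF, with band edges interpolated linearly
in log-frequency at the criterion crossing; a bandwidth whose level row
would exceed 75 dB is flagged undefined rather than extrapolated.

Latencies are estimated from the pooled 1 ms PSTH of 60 dB tones within
half an octave of CF: onset is the left edge of the first bin exceeding the
spontaneous per-bin mean + 2 SD for two consecutive bins (the SD is floored
at the Poisson value √mean so the rule remains defined when the
pre-stimulus window is quiet); peak is the center of the maximum bin in
0–75 ms. This transparent threshold-crossing rule was chosen over
spike-distance methods; the multiplier, run length and bin width are
configurable. With the defaults the estimator carries a small (+0.5 to
+1 bin) onset bias that cancels in group contrasts; recovery tests verify
the mean recovered onset sits within 1 ms of the injected 14.4 ms and that
an injected +2.5 ms shift is recovered within ±0.5 ms.

## Temporal metrics

Per-burst driven counts use a 5–45 ms window after each burst onset (short
enough never to overlap the next burst at 15 Hz) with the same spontaneous
correction. Steady state is the mean of bursts 3–6 — the protocol's
parenthetical time span ("366–433 ms") cannot be reconstructed from the
burst arithmetic at any of the four rates, so the implementation defines
steady state strictly as "bursts three onwards" and leaves the time-span
phrasing aside. Vector strength is the resultant length of spike phases
(θ = 2π·rate·t) over the interval from burst-1 onset through one period
after burst-6 onset, pooled across the 20 trials (per-trial VS is too noisy
at realistic counts); the Rayleigh statistic is 2·n·VS², with phase locking
declared strictly above 13.8. The paired-pulse ratio is P2/P1 on driven
counts; it is flagged undefined when P1 ≤ 0 and, in `temporal_summary()`,
when P1 fails the same 2-SE reliability convention used for FRA cells — a
ratio over an unmeasurable first-burst response would only propagate noise,
and at low evoked gain the unguarded ratio-of-means acquires a heavy upper
tail.

## Speech windows and the template classifier

Speech-window activity reports spontaneous-corrected driven counts in the
consonant (1–40 ms), vowel (default 40–340 ms; the exact vowel placement is
unstated and configurable) and full (0–400 ms) windows. The leave-one-out
classifier bins each trial at 1 ms over 0–40 ms (the consonant window; the
classifier tradition it follows decodes onset spike timing), builds each
label's template as the mean binned PSTH over that label's remaining 19
trials (all 20 of the other label), and assigns the held-out trial by
smaller Euclidean distance, ties broken by a seeded coin flip; 40 folds per
pair, percent correct over folds. Bins are left-closed, matching every
other window in the package. Bin width, window and smoothing (default
none) are configurable and reported in the result. The stop-consonant panel
averages the six unordered pairs of "dad", "bad", "gad", "tad" per site.

## Group statistics and behavior

Normality screening follows the kurtosis rule (Pearson convention, normal
= 3): leptokurtic samples get the Shapiro–Francia test, others
Shapiro–Wilk. `fit_nested_model()` fits nested random intercepts
(site within animal; the site term is dropped automatically — and noted —
when sites are unreplicated, where it is confounded with the residual).
Gaussian families use REML via lme4; Tweedie (log link), beta and binomial
families are fitted with glmmTMB. A `tweedie-approx` family is also
provided — a Gaussian LMM on log(y + c), c defaulting to half the smallest
positive response — for settings where the exact Tweedie fit is too slow
or fragile; its output is labeled as an approximation. Each fixed term gets
a Type II Wald chi-square (car); group estimated marginal means are
computed on the link scale (emmeans) and back-transformed with the exact
inverse link (`emm_backtransform()`), with Tukey-adjusted pairwise
contrasts. AIC/BIC comparison is exposed as a report
(`model_fit_report()`), not an automatic selector. Calibration note: with
~10 animals per group the asymptotic Wald chi-square for the group term
runs slightly hot (about 0.058–0.067 at nominal 0.05 in the package's null
simulations — the finite-cluster inflation of 2·F(2, 27) against χ²₂), a
property of the test rather than of this implementation.

Go/no-go sessions are scored by event replay: hits are pokes within the
3–4 s hit window of a target; pokes on catch trials or later than the hit
window trigger a 6 s timeout during which pokes are ignored; percent
correct is (hits + correct rejections)/trials. Proficiency requires four
consecutive sessions at ≥75%. Success-paired stimulation counts equal
rewarded hits per session. Weekly performance is compared by two-way
repeated measures ANOVA (group × week, animals as subjects) with
uncorrected degrees of freedom and Bonferroni post hocs; sphericity
correction is deliberately not applied by default. The learning-curve
generator is flat across groups by default, matching the study design's
behavioral outcome (learning across weeks without group differences).

## What the synthetic data does and does not show

The generator reproduces the *statistical* structure the estimators
assume: Poisson spiking, alpha-shaped evoked transients, nested lognormal
gain heterogeneity, group effects on gain/latency/adaptation/jitter, and
20-trial stimulus blocks. It does not emulate non-Poisson interval
structure (bursting, refractoriness), oscillatory or state-dependent
baselines, electrode drift, A1/AAF tonotopic geography, or realistic
speech-evoked spectrotemporal receptive fields. Passing recovery tests
therefore demonstrates that the estimators are unbiased and correctly
calibrated *under the assumed model*, not that they are robust to every
physiological deviation from it.

## Problem sizes and numerical choices

The shipped test and acceptance suites use 21 × 16 tone grids, cohorts of
5–10 animals × 9–30 sites per group, 100–250 Monte-Carlo repetitions for
chance-level and recovery checks, 1000 replicates for mixed-model type-I
calibration, and 10,000 nulls for the Rayleigh false-positive rate — sizes
chosen so the whole suite runs on a laptop-class single core in minutes
while keeping Monte-Carlo error well inside each assertion's tolerance.
Degenerate inputs are handled by flags, not crashes: non-responsive sites,
undefined bandwidths and latencies, P1-unreliable paired-pulse ratios and
zero-variance ANOVA inputs are all marked and excluded from downstream
summaries, and exclusion bookkeeping (analyzed + flagged = input) is
tested. Seeds propagate through a splittable integer hash (`child_seed`)
so that every site × stimulus draw is independently reproducible from one
master seed.
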