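---
title: "walkbeat: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{walkbeat: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

When a walker synchronizes steps to a beat, the stimulus fixes the step rate,
so differences in walking speed across stimuli of identical tempo must come
from stride length — an entrainment of movement *vigor* rather than timing.
`walkbeat` implements the three stages needed to study this: extracting sonic
features that describe metrical fluctuation in the music, measuring walking
speed and cadence from wearable sensors with a metronome-relative
normalization, and relating the two through a feature-selecting regression
with honest generalization estimates. Because the audio stimuli used in such
studies are typically copyrighted commercial recordings and the sensor data
are not public, the package ships synthetic generators that emulate every
input; all tests and the acceptance script run on those.

# Sonic feature extraction

## Frame level

Two frame-level analyses run over the mono waveform (stereo input is averaged
to mono, since every feature definition is single-channel):

* **Subband loudness** — 30 ms frames shifted by 5 ms, Hann-windowed, FFT.
  Six triangular filters on the magnitude-squared spectrum measure band
  energies; loudness is `energy^0.25` and total loudness is the fourth root
  of the summed band energies. The filter centers are 118, 298, 570, 983,
  1609 and 2559 Hz. Only the centers are prescribed; the skirts are a design
  choice: each triangle's vertices sit at the adjacent centers (mel-style),
  so the bank tiles the band gaplessly (adjacent weights sum to one), and the
  outer edges extend geometrically by the mean adjacent-center ratio
  (about 1.85). A Hann window is used because the frames are short and the
  loudness-growth features differentiate the energy track: a rectangular
  window makes that track staircase-like.
* **Note evidence** — 150 ms frames shifted by 20 ms. The analysis grid holds
  the 52 equal-tempered note frequencies `440·2^(k/12)` strictly inside
  (100, 2000) Hz, i.e. k = −25..26. A note's salience is a harmonic sum: the
  maximum spectral magnitude within ±1 quarter-tone of the fundamental plus
  half the corresponding maxima around harmonics 2 and 3. Harmonic sums
  attribute energy to subharmonics (a lone A4 would light up A3 and D3
  through their 2nd and 3rd harmonics), so a *fundamental gate* zeroes any
  note whose fundamental magnitude is below 10 % of the frame's strongest
  grid fundamental. The gate is what makes "number of notes found in a beat
  period" a meaningful quantity — a pure A4 yields exactly one active note.

## Beat level

The stimuli are constructed at a known tempo (130 BPM in the study design),
so the beat tracker does not induce tempo; it fits only the grid *phase*,
chosen to maximize the summed onset strength at the grid points. The onset
strength is the positive forward difference of total loudness; its time base
is advanced by a quarter frame length (7.5 ms) because the growth of a
windowed energy measure peaks that far ahead of the event itself — with the
correction, the recovered grid is unbiased on synthetic metronomes to within
the 5 ms frame hop. The tracker also emits two oscillator outputs: the
normalized projections of the de-meaned onset envelope onto complex
exponentials at 2× and 3× the beat rate (a pure sinusoidal envelope at that
frequency reads 1). The number of beats in a clip is the number of *complete*
inter-beat intervals: a 30 s clip at 130 BPM spans 65 beat periods exactly,
and the onset whose period ends exactly at the clip edge is dropped, giving
the 64-onset convention used throughout. Whether those 64 include the faded
edges is not prescribed anywhere; here they do, and the first/last beats of
music-like stimuli are therefore partially attenuated by the 50 ms fade-in /
100 ms fade-out (tests on per-beat properties exclude the edge beats).

Per beat, 47 features in a fixed registry order:

1. **7 onset growths** — maximum forward loudness difference (total + 6
   subbands) within ±70 ms of the beat time, floored at 0. The window width
   is a tunable (`onset_window`); ±70 ms spans the frame hop comfortably
   while staying under a sixteenth note at 130 BPM. Beats at the clip edge
   use whatever frames exist.
2. **3 event descriptors** — position of the onset peak relative to the beat
   time; event length, the time total loudness stays above half its event
   peak (the half-peak threshold is the conventional −6 dB event width); and
   the skewness (third standardized moment) of the loudness samples in the
   event. Beats with no energy report zeros.
3. **21 period statistics** — mean, standard deviation and temporal center
   of gravity of each loudness series within the inter-beat interval. The
   centroid is normalized to [0, 1] within the interval and defaults to 0.5
   for empty or silent intervals (the symmetric, uninformative value).
4. **10 pitch descriptors** — onset position of the most salient note (first
   frame at half its within-interval maximum salience), then frequency,
   chroma and salience of the three most salient notes ranked by mean
   salience, ties broken toward the lower frequency. Absent notes carry zero
   frequency and salience. Chroma is `round(12·log2(f/440)) mod 12` (A = 0).
5. **6 similarities** — cosine similarity between consecutive beats over six
   subsets: subband onset growths, subband means, subband standard
   deviations, subband centroids, the top-3 note frequencies, and the same
   frequencies folded into one octave. A zero vector on either side gives 0.
   The first beat copies the second's similarities so the matrix stays
   rectangular — the song-level spectra need equal-length patterns, and
   repeating the first genuine value adds no spurious periodicity.

## Song level

Each beat-level feature's per-beat sequence is a signal sampled at the beat
rate; its amplitude spectrum is evaluated at 1/2, 1/3, 1/4 and 1/6 of the
beat rate by direct projection. Two numerical choices matter:

* **De-meaning.** For pattern lengths not divisible by the period (64 beats
  probed at period 3 or 6), the DC component leaks into every probed
  frequency; subtracting the mean removes that contamination. A constant
  pattern then reads exactly 0 everywhere.
* **Normalization 2/N.** A unit-amplitude cosine at the probed period reads
  exactly 1, making evidences comparable across stimuli of different beat
  counts and keeping the regression inputs scale-stable.

For lengths divisible by the period the projection equals the corresponding
DFT bin to 1e−10 (tested against an independent FFT-based oracle).

The 190-entry registry is feature-major (periods 2, 3, 4, 6 per beat-level
feature), then the two oscillator outputs. The numbering is this package's
own deterministic convention: the ids used in prior reports of this analysis
depend on the original extractor implementation and cannot be reproduced
without its audio, so the four headline predictors are addressed by *name*
(`headline_features()`): the period-6 evidence of the similarity of subband
loudness standard deviations, the period-4 evidence of the top-note
salience, the period-6 evidence of the third-note frequency, and the
period-3 evidence of the similarity of subband loudness centroids.

# Gait metrics

* **Speed.** The hip sensor reports heading relative to magnetic north,
  wrapped to [0, 2π). The heading is unwrapped before applying
  `d = |θ_end − θ_start| · r`: a 30 s walk at ordinary speed covers most of
  a lap of the 15 m circle (47.1 m circumference), so the wrapped difference
  alone would be wrong for near-lap and multi-lap walks. Gaps over 1 s make
  a trial unusable; shorter gaps are linearly interpolated.
* **Tempo.** The magnitude spectrum of the de-meaned acceleration norm
  (`√(x²+y²+z²)`; no axis is privileged, and the norm is orientation-free),
  zero-padded so the bin width is 0.5 BPM (transform length 6000 at 50 Hz).
  The peak is searched in a 30–120 strides/min band and doubled, because one
  foot strikes once per stride — half the step cadence.
* **Synchronization.** A trial is synchronized when the walking tempo is
  within ±2 SPM of the stimulus tempo (4 DFT bins); double/half tempo are
  classified analogously, everything else is "other". The study definition —
  step count equals beat count — carries no explicit tolerance; ±2 SPM
  accepts one missed or added step per 30 s trial.
* **Normalization.** Only synchronized trials count. Per participant, song
  speeds are divided by the mean speed over that participant's acceptable
  metronome trials and scaled by 100; the per-song speed v_s is the mean
  over participants. Metronome trials therefore map to exactly 100 units by
  construction (the identity the acceptance script checks), and any
  participant-level speed scaling cancels. Participants without an
  acceptable metronome trial are excluded with a warning.

# The speed model

Pre-selection fits all p(p−1)/2 two-feature models (17,955 for 190) in
closed form from the correlation matrix — the correlation between a
two-feature OLS fit and the data is the pair's multiple correlation — and
keeps the 10 features most frequent in the top 10 % of pairs (rounded up,
boundary ties included; frequency ties broken toward the better best-pair
correlation). The simpler top-10-|r| variant is available
(`preselect_correlation`) since the two approaches are worth comparing on
any new dataset.

The nested cross-validation uses 10 outer folds (sizes 8×5 + 2×6 for 52
songs; proportional otherwise) assigned at random from a required seed — the
original assignment of any given study is unknowable, so the seed is an
explicit input. Per trial, pre-selection sees only the development folds;
all 1023 non-empty subsets of the 10 pre-selected features are scored by
9-fold cross-validated RMSE on the development set (RMSE rather than any
other loss, to match the headline quality measure); near-ties (within 1e−9
relative) resolve toward the smaller subset, which keeps noiseless planted
data from dragging in zero-weight passengers. The best subset, refit on the
full development set, predicts the held-out fold. Features enter
unstandardized — evidences are already on a common scale by the 2/N
normalization — with an optional z-score switch in `fit_linear`. The final
model uses the K most frequently selected features, K being the largest
subset ever chosen in a trial.

Explained variance is reported as the square of the pooled Pearson
correlation, so the two quality measures are consistent by construction.

# Group statistics

The activating and relaxing groups are the ten fastest and ten slowest
songs; "the ten most neutral from the middle" is made precise as the ten
ranks centered on the median (ranks 22–31 of 52). The one-way ANOVA uses
`stats::aov`; the Scheffé pairwise contrasts are computed in closed form
(`F = Δ²/(MSE·(1/n_i+1/n_j))/(k−1)` against `F(k−1, df_error)`) since no
installed package exposes them directly. Feature comparisons use Welch
t-tests; adjective ratings use Mann–Whitney tests with exact p-values where
ties permit (a switch selects the normal approximation). P-values are
reported raw, as is conventional for this design, with a Holm-adjusted
column alongside.

# Synthetic generators: what they do and do not emulate

* **Stimuli.** Metronomes are deterministic 1 kHz pips (10 ms, 2 ms ramps)
  at `k·60/tempo`; music-like stimuli place 1–3 grid-note tones on each beat
  with per-beat amplitude `1 + mod_depth·cos(2πb/mod_period)` and the study
  fades. These plant a *known* metrical periodicity but contain none of the
  timbral variety, melody, or expressive timing of real recordings — passing
  recovery tests shows the analysis chain is correct, not that real music
  carries such clean periodicities.
* **Walking.** Heading advances at `speed/radius` with Gaussian noise and is
  emitted wrapped; foot acceleration carries one Gaussian burst per stride.
  Real gait has asymmetries, drift and turning artifacts not modeled here.
* **Planted speed datasets.** Non-planted features are independent standard
  normals; the planted block is centered, orthonormalized in-sample and
  rescaled to unit standard deviation, so the planted effect sizes are
  realized exactly rather than perturbed by sampling collinearity — the
  planted model is identifiable by construction, which is what
  parameter-recovery tests require. Default: 52 songs, 190 features, 4
  planted features with coefficients (6, −5, 5, −7) around intercept 100 —
  effects on the order of half a standard deviation of the speeds, strong
  enough to be reliably detectable at n = 52. Real feature tables are
  heavily collinear (the 188 evidences share 47 parents); recovery results
  on the synthetic tables do not transfer to that regime.
* **Ratings.** Five of the nine adjective pairs (good–bad,
  tender–aggressive, soft–loud, slow–fast, stuttering–flowing) carry a
  planted activating-vs-relaxing shift of 20 points on the 0–100 scale, the
  others none; the design mirrors which pairs a vigor-entrainment account
  predicts to differ. Note the stuttering–flowing pair has its activating
  pole at 0, so its shift is negative.
* **Cohorts.** Participant baseline speeds are N(1.3, 0.08) m/s with
  multiplicative song effects shared across participants; metronome trials
  use the baseline itself, so the normalization identity is exact.

# Problem sizes and determinism

The shipped tests run the extractor on 15–30 s stimuli, the nested CV on
52×190 tables (about two seconds per run), the permutation null over 20
seeds and the selection-leakage check over 10 seeds; the whole suite
completes in under two minutes on one core. Every stochastic component
draws from an explicit integer seed through one RNG helper that restores
the caller's RNG state, so identical inputs give bit-identical outputs —
reruns of `run_all` produce byte-identical feature tables.

# Known limitations

* The extractor's filter skirts, salience rule and oscillator formulation
  are declared substitutes for the corresponding components of the original
  (unpublished) feature extractor, not reconstructions; registry ids are
  package-local.
* The beat tracker assumes the nominal tempo is correct and only fits phase;
  it is not a general-purpose tracker for unknown-tempo audio.
* Headline empirical quantities from the motivating study (prediction RMSE
  near 4 units, correlation near 0.77, the specific group means, the 88.7 %
  synchronization rate) depend on the original copyrighted recordings and
  participant data; the package reproduces the *procedure* and validates it
  on synthetic data, and makes no claim to reproduce those numbers.
* Only the spectral cadence estimate is implemented — no step-event
  detection, and no vertical or lateral movement analysis.
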