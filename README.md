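# walkbeat

Music with a fixed tempo can still change how people walk to it. When walkers
synchronize their steps to a 130 BPM beat, the step *rate* is pinned by the
stimulus, so any change in walking speed must come from stride length — a
vigor response to the music rather than a timing response. `walkbeat`
implements the full analysis pipeline for studying this effect, for
researchers in music cognition, movement science and sports/rehabilitation
applications:

- **Sonic feature extraction.** A three-level extractor turns a 30 s audio
  stimulus into a 190-dimensional feature vector. Frame level: total and
  six-subband loudness (`loudness = energy^0.25`, 30 ms frames / 5 ms hop;
  triangular filters centered at 118, 298, 570, 983, 1609 and 2559 Hz) and
  pitch-salience evidence on a 52-note equal-tempered grid spanning 0.1–2 kHz
  (150 ms frames / 20 ms hop). Beat level: 47 descriptors per inter-beat
  interval (7 onset loudness growths, 3 event descriptors, 21 loudness
  statistics, 10 pitch descriptors, 6 inter-beat cosine similarities). Song
  level: each beat-level pattern x_b is read as a signal sampled at the beat
  rate, and its amplitude spectrum is evaluated at 1/2, 1/3, 1/4 and 1/6 of
  the beat rate,

      evidence(p) = (2/N) |Σ_b (x_b − x̄) e^(−2πi b / p)| ,  p ∈ {2, 3, 4, 6},

  giving 4 × 47 = 188 metrical periodicity evidences, plus two beat-tracker
  oscillator outputs (resonance at 2× and 3× the beat rate) — 190 features.

- **Gait metrics.** Walking distance from the unwrapped hip heading angle
  (`d = |θ_end − θ_start| · r`, circle radius r = 7.5 m), walking tempo from
  the cadence peak of the foot-acceleration spectrum (DFT bins of 0.5 BPM,
  peak doubled to convert strides to steps), synchronization classification
  (sync / double / half / other), and metronome normalization: each
  participant's song speeds are divided by their mean metronome speed, so the
  metronome baseline is 100 units by construction.

- **Speed modelling.** Pairwise feature pre-selection (all 17,955 pairs of
  190 features; the 10 features most frequent in the best 10 % of pairs),
  10-fold outer / 9-fold inner nested cross-validation over all 1023 subsets
  of the pre-selected features, pooled RMSE / Pearson correlation, and a
  final K-feature model.

- **Group statistics.** Activating / relaxing / neutral extreme groups
  (10/10/10), one-way ANOVA with Scheffé post-hoc contrasts on speeds,
  per-feature t-tests, and Mann–Whitney tests on nine bipolar-adjective
  rating pairs.

- **Synthetic data.** Generators for beat-locked audio with planted metrical
  modulation, circular-walk sensor traces with known speed and cadence,
  song-by-feature tables with a planted sparse linear speed model, and
  ratings with planted group shifts — every stage is testable without any
  recorded data.

## Worked example

```r
library(walkbeat)

# a 30 s, 130 BPM stimulus whose loudness swells every 3 beats
stim <- make_modulated_stimulus(
  stimulus_spec(tempo = 130, duration = 30, mod_period = 3,
                mod_depth = 0.5, seed = 42))
sv <- extract_song_features(stim$clip)
round(sv$values[paste0("total_mean_p", c(2, 3, 4, 6))], 3)
#> total_mean_p2 total_mean_p3 total_mean_p4 total_mean_p6
#>         0.002         1.758         0.108         0.048
```

The period-3 evidence of the mean-loudness pattern (1.758) dwarfs the other
probed periods: the song-level analysis has recovered the planted ternary
fluctuation from the audio alone.

```r
# a planted 4-feature speed model through the full nested CV
d <- simulate_speed_dataset(planted_model_spec(noise_sd = 1, seed = 42))
rep <- nested_cv(d$features, d$speeds, seed = 1)
rep
#> <cv_report> 52 songs, 10 trials | RMSE 1.388, PCC 0.993 (R^2 0.986)
final_model(d$features, d$speeds, rep)
#> <regression_model> 6 features, intercept 100.024
#>    f178    f010    f120    f045    f166    f185
#> -7.0034  5.9706  5.1823 -5.0934  0.3132  0.1554
```

The planted features (f010, f045, f120, f178 with coefficients 6, −5, 5, −7)
are recovered with near-exact coefficients; the two spurious entries carry
near-zero weight. Speeds are in percent of the participant's metronome
baseline, so an RMSE of 1.4 means predictions are typically 1.4 % off.

```r
# a simulated walker read back through the gait metrics
g <- gait_result(simulate_walk_trial(walk_spec(speed = 1.4, cadence = 130,
                                               seed = 42)))
#> speed 1.400 m/s, tempo 130.0 SPM, class sync
```

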