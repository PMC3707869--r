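test_that("beat tracking recovers metronome tick times within 10 ms", {
  spec <- stimulus_spec(tempo = 130, duration = 30)
  grid <- track_beats(make_metronome(spec))
  expect_length(grid$beat_times, 64)
  expect_lt(max(abs(grid$beat_times - beat_onset_times(spec))), 0.010)
})

test_that("a silent clip yields a zero-anchored grid and zero oscillators", {
  grid <- track_beats(silence_clip(5), nominal_tempo = 120)
  expect_equal(grid$beat_times[1], 0)
  expect_equal(grid$oscillator_2x, 0)
  expect_equal(grid$oscillator_3x, 0)
})

test_that("beat subdivision drives the 2x oscillator above the 3x", {
  spec <- stimulus_spec(tempo = 130, duration = 15)
  clip <- make_metronome(spec)
  x <- clip$samples
  tick <- walkbeat:::tick_waveform(clip$sample_rate)
  for (tb in beat_onset_times(spec) + 30 / 130) {   # halfway through beats
    i0 <- round(tb * clip$sample_rate) + 1L
    idx <- i0:min(i0 + length(tick) - 1L, length(x))
    x[idx] <- x[idx] + tick[seq_along(idx)]
  }
  grid <- track_beats(audio_clip(x, clip$sample_rate, 130))
  expect_gt(grid$oscillator_2x, grid$oscillator_3x)
  # triplet subdivision flips the ordering
  y <- clip$samples
  for (off in c(1, 2) * 20 / 130) {
    for (tb in beat_onset_times(spec) + off) {
      i0 <- round(tb * clip$sample_rate) + 1L
      idx <- i0:min(i0 + length(tick) - 1L, length(y))
      y[idx] <- y[idx] + tick[seq_along(idx)]
    }
  }
  grid3 <- track_beats(audio_clip(y, clip$sample_rate, 130))
  expect_gt(grid3$oscillator_3x, grid3$oscillator_2x)
})

test_that("onset growths are zero on silence and positive on ticks", {
  spec <- stimulus_spec(tempo = 60, duration = 4, n_beats = 4)
  clip <- make_metronome(spec)
  loud <- subband_loudness(clip)
  grid <- beat_grid(beat_onset_times(spec), 60)
  on <- beat_onset_features(loud, grid)
  expect_identical(dim(on), c(4L, 7L))
  # the first beat sits at the clip edge with no pre-onset frame, so its
  # growth is computed on the available frames only
  expect_true(all(on[-1, "growth_total"] > 0))
  expect_true(all(on >= 0))

  silent <- beat_onset_features(subband_loudness(silence_clip(4)), grid)
  expect_true(all(silent == 0))
})

test_that("event position tracks a tick delayed from the grid point", {
  sr <- 22050
  delay <- 0.030
  x <- numeric(4 * sr)
  tick <- walkbeat:::tick_waveform(sr)
  for (tb in (0:3) + delay) {
    i0 <- round(tb * sr) + 1L
    x[i0:(i0 + length(tick) - 1L)] <- tick
  }
  loud <- subband_loudness(audio_clip(x, sr))
  grid <- beat_grid(0:3, 60)
  ev <- beat_event_features(loud, grid)
  expect_lt(abs(mean(ev[, "event_position"]) - delay), 0.012)
})

test_that("event length grows with the sustain of the beat event", {
  sr <- 22050
  sustained <- function(len_s) {
    x <- numeric(4 * sr)
    for (tb in 0:3) {
      i0 <- round(tb * sr) + 1L
      n <- round(len_s * sr)
      x[i0:(i0 + n - 1L)] <- 0.5 * sin(2 * pi * 880 * (0:(n - 1)) / sr)
    }
    audio_clip(x, sr)
  }
  grid <- beat_grid(0:3, 60)
  lens <- vapply(c(0.05, 0.15, 0.30), function(l) {
    mean(beat_event_features(subband_loudness(sustained(l)),
                             grid)[, "event_length"])
  }, numeric(1))
  expect_true(all(diff(lens) > 0))
})

test_that("a symmetric triangular event has near-zero skewness", {
  ramp <- c(seq(0, 1, length.out = 11), seq(1, 0, length.out = 11)[-1])
  L <- fake_loudness(matrix(rep(c(ramp, numeric(80)), 7), ncol = 7,
                            dimnames = list(NULL, c("total",
                                                    paste0("band", 1:6)))))
  grid <- beat_grid(c(0.05, 0.55), 120)
  ev <- beat_event_features(L, grid)
  expect_lt(abs(ev[1, "event_skewness"]), 0.2)
})

test_that("beat-period statistics follow their definitions", {
  nm <- c("total", paste0("band", 1:6))
  const <- fake_loudness(matrix(2, nrow = 100, ncol = 7,
                                dimnames = list(NULL, nm)))
  grid <- beat_grid(c(0, 0.25), 240)
  pf <- beat_period_features(const, grid)
  expect_identical(dim(pf), c(2L, 21L))
  expect_true(all(pf[, grepl("_sd$", colnames(pf))] == 0))
  expect_equal(unname(pf[, "total_cog"]), rep(0.5, 2), tolerance = 0.05)

  # loudness concentrated in the first half of the interval pulls the
  # centroid below 0.5
  m <- matrix(0, nrow = 100, ncol = 7, dimnames = list(NULL, nm))
  m[1:20, ] <- 1
  front <- beat_period_features(fake_loudness(m), beat_grid(c(0, 0.5), 120))
  expect_lt(front[1, "total_cog"], 0.4)
})

test_that("pitch features report the top notes with zero-filled absences", {
  g <- note_grid()
  # single sustained note at 440 Hz for one beat
  ev <- matrix(0, nrow = 50, ncol = 52)
  ev[, which(g == 440)] <- 1
  pf <- beat_pitch_features(fake_evidence(ev), beat_grid(c(0, 0.5), 120))
  expect_equal(unname(pf[1, "freq1"]), 440)
  expect_equal(unname(pf[1, "chroma1"]), 0)
  expect_equal(unname(pf[1, c("freq3", "sal3")]), c(0, 0))

  # three equal-salience notes: all slots filled, ordered low to high
  ev3 <- matrix(0, nrow = 50, ncol = 52)
  ev3[, c(30, 10, 20)] <- 1
  pf3 <- beat_pitch_features(fake_evidence(ev3), beat_grid(c(0, 0.5), 120))
  expect_equal(unname(pf3[1, c("freq1", "freq2", "freq3")]),
               g[c(10, 20, 30)])
  # no notes at all
  pf0 <- beat_pitch_features(fake_evidence(matrix(0, 50, 52)),
                             beat_grid(c(0, 0.5), 120))
  expect_true(all(pf0 == 0))
})

test_that("similarity features are 1 for identical and 0 for orthogonal", {
  nm_onset <- c("growth_total", paste0("growth_band", 1:6))
  nm_period <- as.vector(t(outer(c("total", paste0("band", 1:6)),
                                 c("_mean", "_sd", "_cog"), paste0)))
  nm_pitch <- c("pitch_onset_pos",
                as.vector(outer(c("freq", "chroma", "sal"), 1:3,
                                paste0)))
  onset <- matrix(1, 4, 7, dimnames = list(NULL, nm_onset))
  period <- matrix(2, 4, 21, dimnames = list(NULL, nm_period))
  pitch <- matrix(440, 4, 10, dimnames = list(NULL, nm_pitch))
  sim <- beat_similarity_features(onset, period, pitch)
  expect_identical(dim(sim), c(4L, 6L))
  expect_true(all(sim == 1))

  # orthogonal consecutive onset-growth vectors
  onset2 <- onset
  onset2[c(1, 3), 2:4] <- 0
  onset2[c(2, 4), 5:7] <- 0
  sim2 <- beat_similarity_features(onset2, period, pitch)
  expect_true(all(sim2[2:4, "sim_growths"] == 0))

  # zero vector on one side is flagged as similarity 0
  onset3 <- onset
  onset3[2, ] <- 0
  expect_equal(unname(beat_similarity_features(onset3, period,
                                               pitch)[2, "sim_growths"]), 0)
})

test_that("an A-A-B-B loudness alternation makes similarities period 2", {
  nm_onset <- c("growth_total", paste0("growth_band", 1:6))
  A <- c(1, 1, 0, 0, 0, 0)
  B <- c(0, 0, 0, 0, 1, 1)
  onset <- cbind(1, rbind(A, A, B, B, A, A, B, B))
  colnames(onset) <- nm_onset
  period <- matrix(1, 8, 21,
                   dimnames = list(NULL,
                                   as.vector(t(outer(c("total",
                                                       paste0("band", 1:6)),
                                                     c("_mean", "_sd",
                                                       "_cog"), paste0)))))
  pitch <- matrix(440, 8, 10,
                  dimnames = list(NULL,
                                  c("pitch_onset_pos",
                                    as.vector(outer(c("freq", "chroma",
                                                      "sal"), 1:3,
                                                    paste0)))))
  s <- beat_similarity_features(onset, period, pitch)[, "sim_growths"]
  expect_equal(unname(s[2:8]), c(1, 0, 1, 0, 1, 0, 1))
  expect_gt(periodicity_evidence(s, 2), periodicity_evidence(s, 4))
})

test_that("the assembled matrix has the 47-column registry layout", {
  stim <- make_modulated_stimulus(
    stimulus_spec(duration = 15, mod_period = 4, mod_depth = 0.5, seed = 6))
  bfm <- beat_feature_matrix(stim$clip)
  expect_identical(ncol(bfm$features), 47L)
  expect_identical(colnames(bfm$features), beat_feature_names())
  expect_identical(nrow(bfm$features), length(bfm$grid$beat_times))
  sims <- bfm$features[, grepl("^sim_", colnames(bfm$features))]
  expect_true(all(sims >= -1 & sims <= 1))
  expect_true(all(bfm$features[, grepl("_mean$|_sd$", colnames(bfm$features))]
                  >= 0))
  expect_true(all(bfm$features[, grepl("^chroma", colnames(bfm$features))]
                  %in% 0:11))
})

test_that("an unmodulated stimulus yields near-identical beat rows", {
  stim <- make_modulated_stimulus(
    stimulus_spec(duration = 15, mod_period = "none", seed = 8))
  bfm <- beat_feature_matrix(stim$clip)
  m <- bfm$features[3:(nrow(bfm$features) - 2), ]   # clear of the fades
  rel_spread <- apply(m, 2, function(col) {
    sd(col) / (abs(mean(col)) + 0.1)
  })
  # residual spread stems from the 5 ms frame quantization of beat onsets
  # and the salience gate flickering on near-threshold partials
  expect_lt(max(rel_spread), 0.15)
  expect_lt(median(rel_spread), 0.02)
})
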