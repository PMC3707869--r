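test_that("standard stimulus spec carries 64 beats and validates inputs", {
  spec <- stimulus_spec(tempo = 130, duration = 30)
  expect_identical(spec$n_beats, 64L)
  expect_equal(beat_onset_times(spec), (0:63) * 60 / 130)
  expect_error(stimulus_spec(tempo = 0), "invalid spec")
  expect_error(stimulus_spec(duration = -1), "invalid spec")
  expect_error(stimulus_spec(mod_period = 5), "invalid spec")
  expect_error(stimulus_spec(mod_depth = 1.5), "invalid spec")
  expect_error(stimulus_spec(notes_per_beat = 4), "invalid spec")
})

test_that("metronome ticks sit at k*60/tempo with silence in between", {
  spec <- stimulus_spec(tempo = 60, duration = 10, n_beats = 10)
  clip <- make_metronome(spec)
  sr <- clip$sample_rate
  active <- which(abs(clip$samples) > 0)
  # onset of each tick = start of each active run
  starts <- active[c(TRUE, diff(active) > 1)]
  expect_length(starts, 10)
  expect_equal((starts - 1) / sr, 0:9, tolerance = 1e-3)
  # digital silence between ticks: blank out tick windows, rest must be 0
  x <- clip$samples
  for (s in starts) x[s:min(s + round(0.011 * sr), length(x))] <- 0
  expect_equal(sqrt(mean(x^2)), 0)
})

test_that("stimulus generation is deterministic given the spec", {
  spec <- stimulus_spec(tempo = 130, duration = 5, mod_period = 3,
                        mod_depth = 0.4, seed = 11)
  a <- make_modulated_stimulus(spec)
  b <- make_modulated_stimulus(spec)
  expect_identical(a$clip$samples, b$clip$samples)
  expect_identical(make_metronome(spec)$samples,
                   make_metronome(spec)$samples)
})

test_that("per-beat RMS of a modulated stimulus has the planted period", {
  for (p in c(2, 3, 4, 6)) {
    stim <- make_modulated_stimulus(
      stimulus_spec(duration = 15, mod_period = p, mod_depth = 0.5,
                    seed = p))
    ann <- stim$annotation
    ibi <- 60 / ann$tempo
    interior <- 2:(length(ann$beat_times) - 2)   # clear of the fades
    r <- beat_rms(stim$clip, ann$beat_times[interior], ibi)
    x <- r - mean(r)
    # autocorrelation oracle: planted lag must dominate the probed lags
    ac <- vapply(c(2, 3, 4, 6), function(l) {
      n <- length(x)
      sum(x[1:(n - l)] * x[(l + 1):n]) / sum(x^2)
    }, numeric(1))
    expect_equal(c(2, 3, 4, 6)[which.max(ac)], p)
  }
})

test_that("unmodulated beats are acoustically identical up to noise", {
  stim <- make_modulated_stimulus(
    stimulus_spec(duration = 15, mod_period = "none", seed = 4))
  ann <- stim$annotation
  interior <- 2:(length(ann$beat_times) - 2)
  r <- beat_rms(stim$clip, ann$beat_times[interior], 60 / ann$tempo)
  expect_lt(sd(r) / mean(r), 0.01)
  expect_true(all(ann$beat_amplitudes == 1))
})

test_that("simulated walk trials carry recoverable ground truth", {
  still <- simulate_walk_trial(walk_spec(speed = 0, heading_noise_sd = 0.01,
                                         seed = 2))
  expect_lt(diff(range(still$heading_rad)), 0.1)
  expect_equal(still$truth$distance, 0)

  tr <- simulate_walk_trial(walk_spec(speed = 1.5, radius = 7.5,
                                      duration = 30))
  expect_equal(tr$truth$distance, 45)

  # one foot strikes once per stride: burst count matches cadence / 2
  quiet <- simulate_walk_trial(walk_spec(cadence = 130,
                                         heading_noise_sd = 0,
                                         acc_noise_sd = 0))
  z <- quiet$acc[, 3]
  peaks <- which(diff(sign(diff(z))) == -2) + 1
  n_bursts <- sum(z[peaks] > max(z) / 2)
  expect_lt(abs(n_bursts - 130 / 2 * 30 / 60), 1.5)
})

test_that("walk spec validation rejects impossible parameters", {
  expect_error(walk_spec(speed = -1), "invalid spec")
  expect_error(walk_spec(cadence = 0), "invalid spec")
  expect_error(walk_spec(radius = 0), "invalid spec")
})

test_that("trial CSVs round-trip with identifiers in the file name", {
  tr <- simulate_walk_trial(walk_spec(seed = 9), participant_id = "P07",
                            stimulus_id = "S13", stimulus_kind = "metronome")
  dir <- withr::local_tempdir()
  path <- write_trial_csv(tr, dir)
  back <- read_trial_csv(path)
  expect_identical(back$participant_id, "P07")
  expect_identical(back$stimulus_id, "S13")
  expect_identical(back$stimulus_kind, "metronome")
  expect_equal(back$heading_rad, tr$heading_rad, tolerance = 1e-9)
  expect_equal(back$sample_rate, 50, tolerance = 1e-6)
})

test_that("planted speed datasets validate and recover noiselessly", {
  expect_error(planted_model_spec(true_feature_ids = c(1, 1),
                                  coefficients = c(1, 2)), "distinct")
  expect_error(planted_model_spec(true_feature_ids = c(1, 500),
                                  coefficients = c(1, 2)), "registry")
  expect_error(planted_model_spec(n_songs = 4), "at least")

  spec <- planted_model_spec(n_songs = 20, true_feature_ids = c(3, 7),
                             coefficients = c(2, -1.5), noise_sd = 0,
                             n_features = 12, seed = 5)
  d <- simulate_speed_dataset(spec)
  fit <- lm(d$speeds ~ d$features[, c(3, 7)])
  expect_equal(unname(coef(fit)), c(100, 2, -1.5), tolerance = 1e-10)
})

test_that("synthetic ratings plant shifts on exactly five adjective pairs", {
  act <- sprintf("A%02d", 1:10)
  rel <- sprintf("R%02d", 1:10)
  m <- simulate_ratings(act, rel, shift = 25, seed = 3)
  expect_identical(dim(m), c(20L, 9L))
  expect_true(all(m >= 0 & m <= 100))
  d <- colMeans(m[act, ]) - colMeans(m[rel, ])
  shifted <- c("good_bad", "tender_aggressive", "soft_loud", "slow_fast")
  expect_true(all(d[shifted] > 10))
  expect_lt(d["stuttering_flowing"], -10)   # activating pole is at 0
  unshifted <- setdiff(adjective_pairs(),
                       c(shifted, "stuttering_flowing"))
  expect_true(all(abs(d[unshifted]) < 10))
})

test_that("WAV files round-trip in both encodings", {
  clip <- audio_clip(0.8 * sin(2 * pi * 440 * (0:999) / 8000), 8000,
                     nominal_tempo = 130)
  dir <- withr::local_tempdir()
  p16 <- file.path(dir, "t16.wav")
  pf <- file.path(dir, "tf.wav")
  write_wav(clip, p16, format = "pcm16")
  write_wav(clip, pf, format = "float32")
  b16 <- read_wav(p16, nominal_tempo = 130)
  bf <- read_wav(pf)
  expect_equal(b16$sample_rate, 8000)
  expect_equal(b16$samples, clip$samples, tolerance = 1e-4)
  expect_equal(bf$samples, clip$samples, tolerance = 1e-6)
  expect_equal(b16$nominal_tempo, 130)
})
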