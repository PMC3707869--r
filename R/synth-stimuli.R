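#' Specification of a synthetic beat-locked stimulus
#'
#' Describes a metronome sequence or a tone stimulus whose per-beat amplitude
#' is modulated with a controllable metrical period. The defaults reproduce
#' the study conditions: 130 BPM, 30 s, hence 64 beat onsets.
#'
#' @param tempo stimulus tempo in beats per minute.
#' @param duration clip duration in seconds.
#' @param n_beats number of beat onsets; defaults to the number of complete
#'   inter-beat intervals inside `duration` (64 at 130 BPM / 30 s).
#' @param mod_period metrical modulation period in beats: `"none"`, 2, 3, 4
#'   or 6.
#' @param mod_depth relative loudness modulation depth in \[0, 1\].
#' @param notes_per_beat number of simultaneous tones per beat (1, 2 or 3).
#' @param seed integer seed governing all randomness in generation.
#' @param sample_rate audio sampling rate in Hz (22050 or 44100).
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(tempo = 130, duration = 30, n_beats = NULL,
                          mod_period = "none", mod_depth = 0,
                          notes_per_beat = 1, seed = 1,
                          sample_rate = 22050) {
  if (!is.numeric(tempo) || tempo <= 0) stop("invalid spec: tempo must be > 0")
  if (!is.numeric(duration) || duration <= 0) {
    stop("invalid spec: duration must be > 0")
  }
  mp <- if (identical(mod_period, "none") || is.na(mod_period)) "none"
        else as.numeric(mod_period)
  if (!identical(mp, "none") && !mp %in% c(2, 3, 4, 6)) {
    stop("invalid spec: mod_period must be one of none, 2, 3, 4, 6")
  }
  if (mod_depth < 0 || mod_depth > 1) {
    stop("invalid spec: mod_depth must lie in [0, 1]")
  }
  if (!notes_per_beat %in% 1:3) {
    stop("invalid spec: notes_per_beat must be 1, 2 or 3")
  }
  if (is.null(n_beats)) n_beats <- beats_in_duration(duration, tempo)
  structure(
    list(tempo = tempo, duration = duration, n_beats = as.integer(n_beats),
         mod_period = mp, mod_depth = mod_depth,
         notes_per_beat = as.integer(notes_per_beat),
         seed = as.integer(seed), sample_rate = sample_rate),
    class = "stimulus_spec"
  )
}

# 1 kHz tone pip: 10 ms long with 2 ms linear ramps. Broadband enough in onset
# for the loudness-growth features, and fully deterministic.
tick_waveform <- function(sample_rate, freq = 1000, length_s = 0.010,
                          ramp_s = 0.002, amplitude = 0.9) {
  n <- round(length_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  env <- rep(1, n)
  nr <- round(ramp_s * sample_rate)
  if (nr > 0) {
    env[seq_len(nr)] <- seq(0, 1, length.out = nr)
    env[(n - nr + 1):n] <- seq(1, 0, length.out = nr)
  }
  amplitude * env * sin(2 * pi * freq * t)
}

#' Generate a metronome sequence
#'
#' Places one short tick (1 kHz pip, 10 ms, 2 ms ramps) at each beat onset
#' `k * 60 / tempo`, `k = 0 .. n_beats - 1`, with digital silence in between.
#' Generation is fully deterministic for a given spec.
#'
#' @param spec a [stimulus_spec()].
#' @return An [audio_clip()] carrying `nominal_tempo`.
#' @export
make_metronome <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  sr <- spec$sample_rate
  n <- round(spec$duration * sr)
  x <- numeric(n)
  tick <- tick_waveform(sr)
  onsets <- beat_onset_times(spec)
  for (t0 in onsets) {
    i0 <- round(t0 * sr) + 1L
    idx <- i0:min(i0 + length(tick) - 1L, n)
    x[idx] <- x[idx] + tick[seq_along(idx)]
  }
  audio_clip(x, sr, nominal_tempo = spec$tempo)
}

#' Beat onset times of a stimulus spec
#' @param spec a [stimulus_spec()].
#' @return Numeric vector of onset times in seconds.
#' @export
beat_onset_times <- function(spec) {
  (seq_len(spec$n_beats) - 1) * 60 / spec$tempo
}

#' Generate a beat-locked tone stimulus with metrical amplitude modulation
#'
#' Each beat carries `notes_per_beat` tones drawn (once, from `seed`) from the
#' 52-note analysis grid; the per-beat amplitude is scaled by
#' `1 + mod_depth * cos(2 * pi * beat / mod_period)`, planting a known
#' periodicity for the song-level analysis to recover. A 50 ms fade-in and
#' 100 ms fade-out are applied, as for the study's music excerpts.
#'
#' @param spec a [stimulus_spec()].
#' @return A list with elements `clip` (an [audio_clip()]) and `annotation`
#'   (beat times, true modulation period and depth, per-beat amplitudes and
#'   the tone frequencies used).
#' @export
make_modulated_stimulus <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  sr <- spec$sample_rate
  n <- round(spec$duration * sr)
  x <- numeric(n)
  grid <- note_grid()
  # mid-grid notes, well inside all subbands and below Nyquist harmonics
  note_freqs <- with_seed(spec$seed, {
    sort(sample(grid[18:40], spec$notes_per_beat))
  })
  onsets <- beat_onset_times(spec)
  b_idx <- seq_along(onsets) - 1
  amps <- if (identical(spec$mod_period, "none")) {
    rep(1, length(onsets))
  } else {
    1 + spec$mod_depth * cos(2 * pi * b_idx / spec$mod_period)
  }
  ibi <- 60 / spec$tempo
  tone_len <- 0.8 * ibi
  nt <- round(tone_len * sr)
  t <- (seq_len(nt) - 1) / sr
  attack <- round(0.005 * sr)
  release <- round(0.020 * sr)
  env <- rep(1, nt)
  env[seq_len(attack)] <- seq(0, 1, length.out = attack)
  env[(nt - release + 1):nt] <- seq(1, 0, length.out = release)
  tone <- rowSums(vapply(note_freqs,
                         function(f) sin(2 * pi * f * t),
                         numeric(nt)))
  tone <- 0.35 / spec$notes_per_beat * env * tone
  for (b in seq_along(onsets)) {
    i0 <- round(onsets[b] * sr) + 1L
    idx <- i0:min(i0 + nt - 1L, n)
    x[idx] <- x[idx] + amps[b] * tone[seq_along(idx)]
  }
  x <- apply_fades(x, sr, fade_in = 0.050, fade_out = 0.100)
  list(
    clip = audio_clip(x, sr, nominal_tempo = spec$tempo),
    annotation = list(beat_times = onsets,
                      mod_period = spec$mod_period,
                      mod_depth = spec$mod_depth,
                      beat_amplitudes = amps,
                      note_freqs = note_freqs,
                      tempo = spec$tempo)
  )
}

apply_fades <- function(x, sample_rate, fade_in = 0.050, fade_out = 0.100) {
  n <- length(x)
  ni <- min(round(fade_in * sample_rate), n)
  no <- min(round(fade_out * sample_rate), n)
  if (ni > 0) x[seq_len(ni)] <- x[seq_len(ni)] * seq(0, 1, length.out = ni)
  if (no > 0) {
    x[(n - no + 1):n] <- x[(n - no + 1):n] * seq(1, 0, length.out = no)
  }
  x
}

#' Write a stimulus annotation JSON sidecar
#' @param annotation annotation list from [make_modulated_stimulus()].
#' @param path output path.
#' @export
write_annotation <- function(annotation, path) {
  jsonlite::write_json(annotation, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
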