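# Small fixtures shared across test files; everything is generated in code.

# Pure-tone clip of the given duration.
tone_clip <- function(freq, duration = 1, sample_rate = 22050, amp = 0.5) {
  t <- (seq_len(round(duration * sample_rate)) - 1) / sample_rate
  audio_clip(amp * sin(2 * pi * freq * t), sample_rate)
}

silence_clip <- function(duration = 1, sample_rate = 22050) {
  audio_clip(numeric(round(duration * sample_rate)), sample_rate)
}

# Hand-built loudness series: a frames x 7 matrix on a regular 5 ms hop.
fake_loudness <- function(loudness, hop = 0.005, frame_len = 0.030) {
  structure(
    list(frame_times = (seq_len(nrow(loudness)) - 1) * hop + frame_len / 2,
         loudness = loudness, frame_len = frame_len, hop = hop),
    class = "loudness_series"
  )
}

# Hand-built note-evidence series on a regular hop.
fake_evidence <- function(evidence, hop = 0.020, frame_len = 0.150) {
  structure(
    list(frame_times = (seq_len(nrow(evidence)) - 1) * hop + frame_len / 2,
         evidence = evidence, note_grid = note_grid(),
         frame_len = frame_len, hop = hop),
    class = "note_evidence_series"
  )
}

# Per-beat RMS of a clip given beat times (interior beats only).
beat_rms <- function(clip, beat_times, ibi) {
  vapply(beat_times, function(tb) {
    i0 <- round(tb * clip$sample_rate) + 1L
    i1 <- min(round((tb + ibi) * clip$sample_rate), length(clip$samples))
    sqrt(mean(clip$samples[i0:i1]^2))
  }, numeric(1))
}
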