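#' Beat grid with beat-tracker oscillator outputs
#'
#' @param beat_times beat onset times in seconds, strictly increasing.
#' @param tempo tempo in BPM.
#' @param oscillator_2x,oscillator_3x resonance evidence at two and three
#'   times the beat rate.
#' @return An object of class `beat_grid`.
#' @export
beat_grid <- function(beat_times, tempo, oscillator_2x = 0,
                      oscillator_3x = 0) {
  stopifnot(all(diff(beat_times) > 0))
  structure(
    list(beat_times = beat_times, tempo = tempo,
         oscillator_2x = oscillator_2x, oscillator_3x = oscillator_3x),
    class = "beat_grid"
  )
}

#' @export
print.beat_grid <- function(x, ...) {
  cat(sprintf("<beat_grid> %d beats at %g BPM (osc 2x %.3f, 3x %.3f)\n",
              length(x$beat_times), x$tempo, x$oscillator_2x,
              x$oscillator_3x))
  invisible(x)
}

# Onset-strength envelope: positive forward difference of the total loudness,
# with times at the midpoints between frame centers plus a quarter frame
# length. The correction undoes the lead of the windowed-energy derivative
# (the growth of a Hann-windowed energy measure peaks about frame_len/4
# before the event itself), so envelope peaks align with event onsets.
onset_envelope <- function(loudness) {
  L <- loudness$loudness[, "total"]
  tt <- loudness$frame_times
  list(times = (tt[-1] + tt[-length(tt)]) / 2 + loudness$frame_len / 4,
       strength = pmax(diff(L), 0))
}

#' Locate the beat grid at a known tempo
#'
#' The stimuli are constructed at a fixed tempo, so only the grid phase is
#' estimated: it is chosen to maximize the summed onset strength at the grid
#' points. The two oscillator outputs are the normalized projections of the
#' de-meaned onset-strength envelope onto complex exponentials at twice and
#' three times the beat rate (a pure sinusoidal envelope at that frequency
#' reads 1).
#'
#' @param clip an [audio_clip()].
#' @param nominal_tempo tempo in BPM; defaults to the clip metadata.
#' @param loudness optional precomputed [subband_loudness()] series.
#' @return A [beat_grid()].
#' @export
track_beats <- function(clip, nominal_tempo = clip$nominal_tempo,
                        loudness = NULL) {
  if (is.null(nominal_tempo)) stop("nominal_tempo is required")
  if (is.null(loudness)) loudness <- subband_loudness(clip)
  env <- onset_envelope(loudness)
  ibi <- 60 / nominal_tempo
  n_beats <- beats_in_duration(clip_duration(clip), nominal_tempo)
  if (n_beats < 1L) stop("clip shorter than one beat period")
  flat <- stats::sd(env$strength) == 0
  phase <- 0
  if (!flat) {
    cand <- seq(0, ibi, length.out = 257L)[-257L]
    score <- vapply(cand, function(p) {
      pts <- p + (seq_len(n_beats) - 1) * ibi
      sum(stats::approx(env$times, env$strength, xout = pts, rule = 2)$y)
    }, numeric(1))
    phase <- cand[which.max(score)]
  }
  beat_times <- phase + (seq_len(n_beats) - 1) * ibi
  osc <- c(0, 0)
  if (!flat) {
    e <- env$strength - mean(env$strength)
    s <- stats::sd(e)
    for (m in c(2, 3)) {
      f <- m * nominal_tempo / 60
      proj <- Mod(sum(e * exp(-2i * pi * f * env$times)))
      osc[m - 1] <- (2 / length(e)) * proj / (sqrt(2) * s)
    }
  }
  beat_grid(beat_times, nominal_tempo, oscillator_2x = osc[1],
            oscillator_3x = osc[2])
}

# Median inter-beat interval of a grid (also used for the last, open-ended
# beat period).
grid_ibi <- function(grid) {
  if (length(grid$beat_times) > 1L) stats::median(diff(grid$beat_times))
  else 60 / grid$tempo
}

#' Beat-onset loudness growths (7 per beat)
#'
#' The loudness growth of each of the 7 series (total + 6 subbands) is the
#' maximum forward difference inside a window of `+/- window` seconds around
#' the beat time, floored at 0.
#'
#' @param loudness a [subband_loudness()] series.
#' @param grid a [beat_grid()].
#' @param window half-width of the onset window in seconds.
#' @return Matrix `n_beats x 7` (`growth_total`, `growth_band1..6`).
#' @export
beat_onset_features <- function(loudness, grid, window = 0.07) {
  g <- apply(loudness$loudness, 2, diff)
  tg <- (loudness$frame_times[-1] +
           loudness$frame_times[-length(loudness$frame_times)]) / 2
  out <- t(vapply(grid$beat_times, function(tb) {
    idx <- which(tg >= tb - window & tg <= tb + window)
    if (length(idx) == 0L) return(numeric(7))
    pmax(apply(g[idx, , drop = FALSE], 2, max), 0)
  }, numeric(7)))
  colnames(out) <- c("growth_total", paste0("growth_band", 1:6))
  out
}

#' Beat-event descriptors (3 per beat)
#'
#' From the total-loudness series: the position of the onset peak relative to
#' the nominal beat time; the length of the beat event, defined as the time
#' the total loudness stays above half its event peak; and the skewness
#' (third standardized moment) of the loudness samples within the event.
#' Beats with no energy yield zeros.
#'
#' @inheritParams beat_onset_features
#' @return Matrix `n_beats x 3` (`event_position`, `event_length`,
#'   `event_skewness`).
#' @export
beat_event_features <- function(loudness, grid, window = 0.07) {
  L <- loudness$loudness[, "total"]
  tt <- loudness$frame_times
  ibi <- grid_ibi(grid)
  out <- t(vapply(grid$beat_times, function(tb) {
    win <- which(tt >= tb - window & tt <= tb + window)
    if (length(win) == 0L || max(L[win]) <= 0) return(numeric(3))
    peak_i <- win[which.max(L[win])]
    position <- tt[peak_i] - tb
    span <- which(tt >= tb - window & tt < tb + ibi)
    above <- L[span] >= 0.5 * L[peak_i]
    # contiguous run of above-half-peak frames containing the peak
    k <- match(peak_i, span)
    lo <- k; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
    hi <- k; while (hi < length(span) && above[hi + 1L]) hi <- hi + 1L
    run <- span[lo:hi]
    c(position, length(run) * loudness$hop, skewness_m3(L[run]))
  }, numeric(3)))
  colnames(out) <- c("event_position", "event_length", "event_skewness")
  out
}

#' Beat-period loudness statistics (21 per beat)
#'
#' Within each inter-beat interval, and for each of the 7 loudness series:
#' the mean, the standard deviation, and the temporal center of gravity of
#' the loudness pattern (first moment of loudness over time, normalized to
#' \[0, 1\] within the interval; 0.5 for an empty or flat interval).
#'
#' @inheritParams beat_onset_features
#' @return Matrix `n_beats x 21` (`<series>_mean`, `<series>_sd`,
#'   `<series>_cog` for `total`, `band1..band6`).
#' @export
beat_period_features <- function(loudness, grid) {
  tt <- loudness$frame_times
  ibi <- grid_ibi(grid)
  bt <- grid$beat_times
  ends <- c(bt[-1], bt[length(bt)] + ibi)
  series <- colnames(loudness$loudness)
  out <- matrix(0, nrow = length(bt), ncol = 21)
  colnames(out) <- as.vector(t(outer(series, c("_mean", "_sd", "_cog"),
                                     paste0)))
  for (b in seq_along(bt)) {
    idx <- which(tt >= bt[b] & tt < ends[b])
    for (j in seq_along(series)) {
      col0 <- (j - 1) * 3
      if (length(idx) == 0L) {
        out[b, col0 + 3] <- 0.5
        next
      }
      l <- loudness$loudness[idx, j]
      u <- pmin(pmax((tt[idx] - bt[b]) / (ends[b] - bt[b]), 0), 1)
      out[b, col0 + 1] <- mean(l)
      out[b, col0 + 2] <- if (length(l) > 1L) stats::sd(l) else 0
      out[b, col0 + 3] <- if (sum(l) > 0) sum(l * u) / sum(l) else 0.5
    }
  }
  out
}

#' Beat-period pitch descriptors (10 per beat)
#'
#' Within each inter-beat interval: the onset position of the most salient
#' note (time, relative to the beat, at which its salience first reaches half
#' its within-interval maximum), followed by the frequency (Hz), pitch class
#' (chroma, 0-11) and salience of the three most salient notes ranked by
#' within-interval mean salience (ties broken toward lower frequency). Absent
#' notes are marked by zero frequency and salience.
#'
#' @param evidence a [note_evidence()] series.
#' @param grid a [beat_grid()].
#' @return Matrix `n_beats x 10` (`pitch_onset_pos`, then
#'   `freq1, chroma1, sal1, ..., sal3`).
#' @export
beat_pitch_features <- function(evidence, grid) {
  tt <- evidence$frame_times
  freqs <- evidence$note_grid
  ibi <- grid_ibi(grid)
  bt <- grid$beat_times
  ends <- c(bt[-1], bt[length(bt)] + ibi)
  out <- matrix(0, nrow = length(bt), ncol = 10)
  colnames(out) <- c("pitch_onset_pos",
                     as.vector(outer(c("freq", "chroma", "sal"), 1:3,
                                     paste0)))
  for (b in seq_along(bt)) {
    idx <- which(tt >= bt[b] & tt < ends[b])
    if (length(idx) == 0L) next
    ev <- evidence$evidence[idx, , drop = FALSE]
    msal <- colMeans(ev)
    found <- which(msal > 0)
    if (length(found) == 0L) next
    found <- found[order(-msal[found], freqs[found])]
    top <- found[seq_len(min(3L, length(found)))]
    s1 <- ev[, top[1]]
    onset_i <- idx[which(s1 >= 0.5 * max(s1))[1]]
    out[b, 1] <- tt[onset_i] - bt[b]
    for (r in seq_along(top)) {
      f <- freqs[top[r]]
      out[b, 1 + (r - 1) * 3 + 1:3] <- c(f, chroma_of(f), msal[top[r]])
    }
  }
  out
}

#' Inter-beat cosine similarity features (6 per beat)
#'
#' Cosine similarity between each beat and its predecessor over six feature
#' subsets: (1) the six subband onset growths, (2) the six subband loudness
#' means, (3) the six subband loudness standard deviations, (4) the six
#' subband loudness centroids, (5) the three most salient note frequencies,
#' and (6) the same frequencies folded to one octave (chroma-mapped). A zero
#' vector on either side yields similarity 0. The first beat's similarities
#' are copied from the second so every beat row is complete.
#'
#' @param onset 7-column matrix from [beat_onset_features()].
#' @param period 21-column matrix from [beat_period_features()].
#' @param pitch 10-column matrix from [beat_pitch_features()].
#' @return Matrix `n_beats x 6` (`sim_growths, sim_means, sim_sds, sim_cogs,
#'   sim_freqs, sim_chromafreqs`).
#' @export
beat_similarity_features <- function(onset, period, pitch) {
  n <- nrow(onset)
  stopifnot(n >= 2L, nrow(period) == n, nrow(pitch) == n)
  band_cols <- function(stat) paste0("band", 1:6, "_", stat)
  freq_cols <- paste0("freq", 1:3)
  subsets <- list(
    sim_growths = onset[, paste0("growth_band", 1:6), drop = FALSE],
    sim_means = period[, band_cols("mean"), drop = FALSE],
    sim_sds = period[, band_cols("sd"), drop = FALSE],
    sim_cogs = period[, band_cols("cog"), drop = FALSE],
    sim_freqs = pitch[, freq_cols, drop = FALSE],
    sim_chromafreqs = apply(pitch[, freq_cols, drop = FALSE], 2,
                            fold_to_octave)
  )
  out <- matrix(0, nrow = n, ncol = 6,
                dimnames = list(NULL, names(subsets)))
  for (j in seq_along(subsets)) {
    m <- subsets[[j]]
    for (b in 2:n) out[b, j] <- cosine_similarity(m[b - 1, ], m[b, ])
  }
  out[1, ] <- out[2, ]
  out
}

#' Names of the 47 beat-level features, in registry order
#' @return Character vector of length 47.
#' @export
beat_feature_names <- function() {
  c("growth_total", paste0("growth_band", 1:6),
    "event_position", "event_length", "event_skewness",
    as.vector(t(outer(c("total", paste0("band", 1:6)),
                      c("_mean", "_sd", "_cog"), paste0))),
    "pitch_onset_pos",
    as.vector(outer(c("freq", "chroma", "sal"), 1:3, paste0)),
    paste0("sim_", c("growths", "means", "sds", "cogs", "freqs",
                     "chromafreqs")))
}

#' Full beat-level feature matrix (47 features per beat)
#'
#' Runs the frame-level analyses, locates the beat grid and assembles the
#' 7 onset growths, 3 event descriptors, 21 period statistics, 10 pitch
#' descriptors and 6 inter-beat similarities into one `n_beats x 47` matrix.
#'
#' @param clip an [audio_clip()].
#' @param nominal_tempo tempo in BPM; defaults to the clip metadata.
#' @param onset_window onset half-window in seconds.
#' @return An object of class `beat_feature_matrix` with elements `features`
#'   (the matrix) and `grid` (the [beat_grid()]).
#' @export
beat_feature_matrix <- function(clip, nominal_tempo = clip$nominal_tempo,
                                onset_window = 0.07) {
  loud <- subband_loudness(clip)
  ev <- note_evidence(clip)
  grid <- track_beats(clip, nominal_tempo, loudness = loud)
  onset <- beat_onset_features(loud, grid, window = onset_window)
  event <- beat_event_features(loud, grid, window = onset_window)
  period <- beat_period_features(loud, grid)
  pitch <- beat_pitch_features(ev, grid)
  sim <- beat_similarity_features(onset, period, pitch)
  m <- cbind(onset, event, period, pitch, sim)
  stopifnot(identical(colnames(m), beat_feature_names()), ncol(m) == 47L)
  structure(list(features = m, grid = grid),
            class = "beat_feature_matrix")
}

#' @export
print.beat_feature_matrix <- function(x, ...) {
  cat(sprintf("<beat_feature_matrix> %d beats x %d features\n",
              nrow(x$features), ncol(x$features)))
  invisible(x)
}

#' Write a beat-feature matrix to CSV with a JSON sidecar
#'
#' @param bfm a [beat_feature_matrix()].
#' @param path CSV output path; the sidecar (beat times, tempo, oscillator
#'   outputs) is written to `<path>.json`.
#' @export
write_beat_features <- function(bfm, path) {
  utils::write.csv(as.data.frame(bfm$features), path, row.names = FALSE)
  jsonlite::write_json(
    list(beat_times = bfm$grid$beat_times, tempo = bfm$grid$tempo,
         oscillator_2x = bfm$grid$oscillator_2x,
         oscillator_3x = bfm$grid$oscillator_3x),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
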