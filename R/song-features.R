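#' Periodicity evidence of a per-beat feature pattern
#'
#' Treats the per-beat values of one beat-level feature as a signal sampled
#' at the beat rate and evaluates its amplitude spectrum at one over `period`
#' of the beat rate by direct projection:
#' `(2/N) * |sum_b (x_b - mean(x)) * exp(-2i * pi * b / period)|`.
#' The pattern is de-meaned first so that DC leakage cannot contaminate the
#' probed frequencies, and the `2/N` normalization makes a unit-amplitude
#' cosine read exactly 1.
#'
#' @param pattern numeric vector, one value per beat.
#' @param period periodicity probed, in beats (2, 3, 4 or 6).
#' @return Non-negative evidence value.
#' @export
periodicity_evidence <- function(pattern, period) {
  if (!period %in% c(2, 3, 4, 6)) {
    stop("period must be one of 2, 3, 4, 6 beats")
  }
  n <- length(pattern)
  if (n < 2 * period) {
    stop("insufficient data: pattern must span at least two periods")
  }
  x <- pattern - mean(pattern)
  b <- seq_len(n) - 1
  (2 / n) * Mod(sum(x * exp(-2i * pi * b / period)))
}

#' The song-level feature registry
#'
#' Enumerates the 190 song-level features: four periodicity evidences (at
#' periods of 2, 3, 4 and 6 beats, in that order) for each of the 47
#' beat-level features, feature-major, followed by the two beat-tracker
#' oscillator outputs. The numbering is deterministic and stable across runs.
#'
#' @return A data frame with columns `id`, `name`, `parent` (beat-level
#'   feature, or `"beat_tracker"`) and `periodicity` (`"2"`, `"3"`, `"4"`,
#'   `"6"`, `"osc_2x"` or `"osc_3x"`).
#' @export
feature_registry <- function() {
  parents <- beat_feature_names()
  periods <- c(2, 3, 4, 6)
  df <- data.frame(
    id = seq_len(190L),
    name = c(as.vector(t(outer(parents, periods,
                               function(p, k) paste0(p, "_p", k)))),
             "osc_2x", "osc_3x"),
    parent = c(rep(parents, each = 4), "beat_tracker", "beat_tracker"),
    periodicity = c(rep(as.character(periods), times = 47),
                    "osc_2x", "osc_3x"),
    stringsAsFactors = FALSE
  )
  df
}

#' Named registry entries for the four headline predictors
#'
#' The four song-level features that the walking-speed analysis singles out,
#' addressed by name rather than by registry number: the period-6 evidence of
#' the similarity of subband loudness standard deviations, the period-4
#' evidence of the top-note salience, the period-6 evidence of the third-note
#' frequency, and the period-3 evidence of the similarity of subband loudness
#' centroids.
#'
#' @return Subset of [feature_registry()] rows with a `role` column.
#' @export
headline_features <- function() {
  reg <- feature_registry()
  want <- c(sim_sds_p6 = "period-6 similarity of subband loudness sds",
            sal1_p4 = "period-4 salience of the most salient note",
            freq3_p6 = "period-6 frequency of the third most salient note",
            sim_cogs_p3 = "period-3 similarity of subband loudness centroids")
  out <- reg[match(names(want), reg$name), ]
  out$role <- unname(want)
  out
}

#' Assemble the 190-dimensional song feature vector
#'
#' Computes the four periodicity evidences for each of the 47 beat-level
#' feature patterns and appends the two oscillator outputs.
#'
#' @param bfm a [beat_feature_matrix()].
#' @param grid a [beat_grid()]; defaults to the one inside `bfm`.
#' @return An object of class `song_feature_vector` with elements `values`
#'   (named numeric vector of length 190) and `registry`.
#' @export
song_vector <- function(bfm, grid = bfm$grid) {
  m <- bfm$features
  if (nrow(m) < 12L) {
    stop("insufficient data: at least 12 beats are required")
  }
  periods <- c(2, 3, 4, 6)
  vals <- as.vector(vapply(seq_len(ncol(m)), function(j) {
    vapply(periods, function(p) periodicity_evidence(m[, j], p), numeric(1))
  }, numeric(4)))
  vals <- c(vals, grid$oscillator_2x, grid$oscillator_3x)
  reg <- feature_registry()
  names(vals) <- reg$name
  structure(list(values = vals, registry = reg),
            class = "song_feature_vector")
}

#' @export
print.song_feature_vector <- function(x, ...) {
  cat(sprintf("<song_feature_vector> %d features\n", length(x$values)))
  invisible(x)
}

#' Extract the full 190-feature song vector from audio
#'
#' Convenience wrapper running the frame-level, beat-level and song-level
#' analyses in sequence.
#'
#' @param clip an [audio_clip()].
#' @param nominal_tempo tempo in BPM; defaults to the clip metadata.
#' @return A [song_vector()].
#' @export
extract_song_features <- function(clip, nominal_tempo = clip$nominal_tempo) {
  bfm <- beat_feature_matrix(clip, nominal_tempo = nominal_tempo)
  song_vector(bfm)
}

#' Write a song-by-feature table to CSV with a JSON registry sidecar
#'
#' @param features matrix or data frame, songs as rows, 190 registry columns.
#' @param path CSV output path; the registry goes to `<path>.registry.json`.
#' @export
write_feature_table <- function(features, path) {
  df <- as.data.frame(features)
  df <- cbind(stimulus_id = rownames(features), df)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(feature_registry(), paste0(path, ".registry.json"),
                       digits = NA)
  invisible(path)
}
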