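#' Walking distance and speed from the hip heading angle
#'
#' The heading (angle with respect to magnetic north, possibly wrapped to
#' \[0, 2*pi)) is unwrapped to a continuous angle; the walked distance is the
#' absolute unwrapped angular excursion times the circle radius, and speed is
#' distance over duration. Unwrapping makes multi-lap walks correct, which
#' the wrapped angle difference alone would not be.
#'
#' @param heading numeric vector of heading angles in radians.
#' @param radius circle radius in m (7.5 m in the study layout).
#' @param duration trial duration in s.
#' @param sample_rate sampling rate in Hz, used to assess gaps.
#' @return List with `distance` (m) and `speed` (m/s).
#' @export
walking_speed <- function(heading, radius = 7.5, duration = 30,
                          sample_rate = 50) {
  if (duration <= 0 || radius <= 0) stop("radius and duration must be > 0")
  if (anyNA(heading)) {
    gap <- rle(is.na(heading))
    if (any(gap$lengths[gap$values] > sample_rate)) {
      stop("unusable trial: heading gap longer than 1 s")
    }
    heading <- stats::approx(seq_along(heading), heading,
                             xout = seq_along(heading), rule = 2)$y
  }
  th <- signal::unwrap(heading)
  distance <- abs(th[length(th)] - th[1]) * radius
  list(distance = distance, speed = distance / duration)
}

#' Walking tempo from foot acceleration
#'
#' Takes the magnitude spectrum of the de-meaned acceleration norm,
#' zero-padded so the DFT bin width equals 0.5 BPM (a transform length of
#' 6000 samples at 50 Hz), locates the peak within a plausible stride band,
#' and doubles the peak frequency to convert strides per minute to steps per
#' minute (one foot strikes once per stride).
#'
#' @param acc acceleration: an `n x 3` matrix (the norm is used) or a vector.
#' @param sample_rate sampling rate in Hz.
#' @param stride_band plausible stride-rate band in strides per minute.
#' @return Walking tempo in steps per minute.
#' @export
walking_tempo <- function(acc, sample_rate = 50, stride_band = c(30, 120)) {
  x <- if (is.matrix(acc)) sqrt(rowSums(acc^2)) else acc
  if (length(x) < 10 * sample_rate) {
    stop("at least 10 s of acceleration signal are required")
  }
  x <- x - mean(x)
  if (stats::sd(x) == 0) stop("no cadence peak: flat acceleration signal")
  nfft <- ceiling(sample_rate * 120)        # bin width = 0.5 BPM
  if (length(x) > nfft) nfft <- length(x)
  sp <- Mod(stats::fft(c(x, numeric(nfft - length(x)))))
  freqs_spm <- (seq_len(nfft) - 1) / nfft * sample_rate * 60
  band <- which(freqs_spm >= stride_band[1] & freqs_spm <= stride_band[2])
  peak <- band[which.max(sp[band])]
  if (sp[peak] <= 0) stop("no cadence peak found")
  2 * freqs_spm[peak]
}

#' Classify walking-stimulus synchronization
#'
#' @param tempo_walk walking tempo in steps per minute.
#' @param tempo_stim stimulus tempo in beats per minute.
#' @param tol tolerance in steps per minute.
#' @return One of `"sync"`, `"double"`, `"half"`, `"other"`.
#' @export
classify_sync <- function(tempo_walk, tempo_stim, tol = 2) {
  stopifnot(tol > 0)
  if (abs(tempo_walk - tempo_stim) <= tol) return("sync")
  if (abs(tempo_walk - 2 * tempo_stim) <= tol) return("double")
  if (abs(tempo_walk - tempo_stim / 2) <= tol) return("half")
  "other"
}

#' Derive gait metrics for one trial
#'
#' @param trial a `trial_record`.
#' @param radius circle radius in m.
#' @param stimulus_tempo stimulus tempo in BPM.
#' @param sync_tol synchronization tolerance in steps per minute.
#' @return An object of class `gait_result`: `distance`, `speed`, `tempo`
#'   and `sync_class`.
#' @export
gait_result <- function(trial, radius = 7.5, stimulus_tempo = 130,
                        sync_tol = 2) {
  ws <- walking_speed(trial$heading_rad, radius = radius,
                      duration = trial$duration,
                      sample_rate = trial$sample_rate)
  tempo <- walking_tempo(trial$acc, sample_rate = trial$sample_rate)
  structure(
    list(distance = ws$distance, speed = ws$speed, tempo = tempo,
         sync_class = classify_sync(tempo, stimulus_tempo, tol = sync_tol)),
    class = "gait_result"
  )
}

#' Tabulate gait results over a list of trials
#'
#' @param trials list of `trial_record`s.
#' @param ... passed to [gait_result()].
#' @return Data frame with one row per trial: participant and stimulus
#'   identifiers, distance, speed, tempo and sync class.
#' @export
gait_table <- function(trials, ...) {
  rows <- lapply(trials, function(tr) {
    g <- gait_result(tr, ...)
    data.frame(participant_id = tr$participant_id,
               stimulus_id = tr$stimulus_id,
               stimulus_kind = tr$stimulus_kind,
               distance = g$distance, speed = g$speed, tempo = g$tempo,
               sync_class = g$sync_class, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Metronome-normalized per-song walking speeds
#'
#' Only acceptable trials (sync class `"sync"`) contribute. Each
#' participant's song-trial speeds are divided by that participant's mean
#' speed over their acceptable metronome trials and scaled by 100, so the
#' metronome baseline equals 100 units by construction. The per-song speed
#' `v_s` is the mean of the normalized values over participants.
#' Participants without an acceptable metronome trial are excluded with a
#' warning.
#'
#' @param results data frame as produced by [gait_table()].
#' @return An object of class `speed_table`: a data frame with columns
#'   `stimulus_id`, `v` and `n_trials`, with attributes
#'   `metronome_mean` (the mean normalized metronome value) and
#'   `participant_factors`.
#' @export
normalize_speeds <- function(results) {
  ok <- results$sync_class == "sync"
  met <- results[ok & results$stimulus_kind == "metronome", ]
  factors <- tapply(met$speed, met$participant_id, mean)
  participants <- unique(results$participant_id)
  missing <- setdiff(participants, names(factors))
  if (length(missing) > 0) {
    warning("excluding participant(s) without acceptable metronome trials: ",
            paste(missing, collapse = ", "))
  }
  acc <- results[ok & results$participant_id %in% names(factors), ]
  acc$normalized <- 100 * acc$speed / as.numeric(factors[acc$participant_id])
  songs <- acc[acc$stimulus_kind == "song", ]
  v <- tapply(songs$normalized, songs$stimulus_id, mean)
  n <- tapply(songs$normalized, songs$stimulus_id, length)
  out <- data.frame(stimulus_id = names(v), v = as.numeric(v),
                    n_trials = as.integer(n), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "metronome_mean") <-
    mean(acc$normalized[acc$stimulus_kind == "metronome"])
  attr(out, "participant_factors") <- factors
  class(out) <- c("speed_table", "data.frame")
  out
}
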