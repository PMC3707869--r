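#' Specification of a simulated circular-path walking trial
#'
#' Defaults mirror the study setup: a 15 m diameter circle (radius 7.5 m),
#' 30 s trials, 50 Hz sensor sampling, and a cadence of 130 steps per minute
#' matching the 130 BPM stimuli.
#'
#' @param speed walking speed in m/s.
#' @param cadence step rate in steps per minute.
#' @param radius circle radius in m.
#' @param duration trial duration in seconds.
#' @param sample_rate sensor sampling rate in Hz.
#' @param heading_noise_sd standard deviation of heading noise in radians.
#' @param acc_noise_sd standard deviation of accelerometer noise in m/s^2.
#' @param seed integer seed.
#' @return An object of class `walk_spec`.
#' @export
walk_spec <- function(speed = 1.4, cadence = 130, radius = 7.5,
                      duration = 30, sample_rate = 50,
                      heading_noise_sd = 0.01, acc_noise_sd = 0.05,
                      seed = 1) {
  if (speed < 0) stop("invalid spec: speed must be >= 0")
  if (cadence <= 0) stop("invalid spec: cadence must be > 0")
  if (radius <= 0) stop("invalid spec: radius must be > 0")
  structure(
    list(speed = speed, cadence = cadence, radius = radius,
         duration = duration, sample_rate = sample_rate,
         heading_noise_sd = heading_noise_sd, acc_noise_sd = acc_noise_sd,
         seed = as.integer(seed)),
    class = "walk_spec"
  )
}

#' Simulate one walking trial's sensor streams
#'
#' Emulates the hip heading sensor (angle with respect to magnetic north,
#' wrapped to \[0, 2*pi)) and the foot accelerometer of a walker moving along
#' a circle. One foot strikes the ground once per stride, so acceleration
#' bursts occur at half the cadence. The generating ground truth (speed,
#' cadence, distance) is stored alongside the streams.
#'
#' @param spec a [walk_spec()].
#' @param participant_id,stimulus_id identifiers attached to the trial.
#' @param stimulus_kind `"song"` or `"metronome"`.
#' @return An object of class `trial_record` with fields `time_s`,
#'   `heading_rad`, `acc` (n x 3 matrix), identifiers and `truth`.
#' @export
simulate_walk_trial <- function(spec, participant_id = "P01",
                                stimulus_id = "S01",
                                stimulus_kind = c("song", "metronome")) {
  stopifnot(inherits(spec, "walk_spec"))
  stimulus_kind <- match.arg(stimulus_kind)
  sr <- spec$sample_rate
  # inclusive end point so the heading excursion spans exactly `duration`
  n <- round(spec$duration * sr) + 1L
  t <- (seq_len(n) - 1) / sr
  with_seed(spec$seed, {
    theta0 <- stats::runif(1, 0, 2 * pi)
    omega <- spec$speed / spec$radius
    heading_true <- theta0 + omega * t
    noise <- if (spec$heading_noise_sd > 0) {
      stats::rnorm(n, 0, spec$heading_noise_sd)
    } else numeric(n)
    heading <- (heading_true + noise) %% (2 * pi)

    # one burst per stride (= 2 steps); Gaussian-windowed impulses on each axis
    stride_hz <- spec$cadence / 2 / 60
    burst_times <- seq(0.1, spec$duration - 0.1, by = 1 / stride_hz)
    burst <- function(amp) {
      y <- numeric(n)
      for (tb in burst_times) {
        y <- y + amp * exp(-0.5 * ((t - tb) / 0.025)^2)
      }
      y
    }
    acc <- cbind(
      acc_x = 0.3 * burst(1) ,
      acc_y = 0.2 * burst(1),
      acc_z = 8 * burst(1)
    )
    if (spec$acc_noise_sd > 0) {
      acc <- acc + matrix(stats::rnorm(3 * n, 0, spec$acc_noise_sd), ncol = 3)
    }
    structure(
      list(participant_id = participant_id, stimulus_id = stimulus_id,
           stimulus_kind = stimulus_kind, time_s = t, heading_rad = heading,
           acc = acc, sample_rate = sr, duration = spec$duration,
           truth = list(speed = spec$speed, cadence = spec$cadence,
                        distance = spec$speed * spec$duration,
                        theta0 = theta0)),
      class = "trial_record"
    )
  })
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> %s / %s (%s), %.1f s at %g Hz\n",
              x$participant_id, x$stimulus_id, x$stimulus_kind,
              x$duration, x$sample_rate))
  invisible(x)
}

#' Write a trial record to CSV
#'
#' The file has columns `time_s, heading_rad, acc_x, acc_y, acc_z`; the
#' participant id, stimulus id and stimulus kind are encoded in the file name
#' as `<participant>__<stimulus>__<kind>.csv`.
#'
#' @param trial a `trial_record`.
#' @param dir output directory.
#' @return The file path, invisibly.
#' @export
write_trial_csv <- function(trial, dir) {
  stopifnot(inherits(trial, "trial_record"))
  path <- file.path(dir, sprintf("%s__%s__%s.csv", trial$participant_id,
                                 trial$stimulus_id, trial$stimulus_kind))
  df <- data.frame(time_s = trial$time_s, heading_rad = trial$heading_rad,
                   acc_x = trial$acc[, 1], acc_y = trial$acc[, 2],
                   acc_z = trial$acc[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trial record from CSV
#'
#' @param path path written by [write_trial_csv()].
#' @param participant_id,stimulus_id,stimulus_kind identifiers; parsed from
#'   the `<participant>__<stimulus>__<kind>.csv` file name when `NULL`.
#' @return A `trial_record` (without ground truth).
#' @export
read_trial_csv <- function(path, participant_id = NULL, stimulus_id = NULL,
                           stimulus_kind = NULL) {
  df <- utils::read.csv(path)
  need <- c("time_s", "heading_rad", "acc_x", "acc_y", "acc_z")
  if (!all(need %in% names(df))) {
    stop("trial CSV must have columns ", paste(need, collapse = ", "))
  }
  parts <- strsplit(sub("\\.csv$", "", basename(path)), "__", fixed = TRUE)[[1]]
  if (is.null(participant_id)) participant_id <- parts[1]
  if (is.null(stimulus_id)) stimulus_id <- parts[2]
  if (is.null(stimulus_kind)) {
    stimulus_kind <- if (length(parts) >= 3) parts[3] else "song"
  }
  dt <- diff(df$time_s)
  sr <- 1 / stats::median(dt)
  structure(
    list(participant_id = participant_id, stimulus_id = stimulus_id,
         stimulus_kind = stimulus_kind, time_s = df$time_s,
         heading_rad = df$heading_rad,
         acc = as.matrix(df[, c("acc_x", "acc_y", "acc_z")]),
         sample_rate = sr, duration = nrow(df) / sr, truth = NULL),
    class = "trial_record"
  )
}

#' Simulate a walking cohort
#'
#' Generates trials for `n_participants` walkers over a playlist of songs and
#' interleaved metronome sequences. Each participant has their own baseline
#' speed; each song carries a multiplicative speed effect shared across
#' participants, emulating activating/relaxing stimuli. Metronome trials use
#' the participant baseline, so normalized metronome speed is 100 by
#' construction.
#'
#' @param n_participants number of walkers.
#' @param n_songs number of song stimuli.
#' @param n_metronomes number of metronome trials per participant.
#' @param song_effects optional numeric vector (length `n_songs`) of relative
#'   speed effects; defaults to Uniform(-0.12, 0.12) draws.
#' @param duration,sample_rate,radius,heading_noise_sd trial parameters, see
#'   [walk_spec()].
#' @param seed integer seed.
#' @return A list with `trials` (list of `trial_record`), `song_effects` and
#'   the participant baseline speeds.
#' @export
simulate_cohort <- function(n_participants = 6, n_songs = 8,
                            n_metronomes = 2, song_effects = NULL,
                            duration = 30, sample_rate = 50, radius = 7.5,
                            heading_noise_sd = 0.005, seed = 1) {
  params <- with_seed(seed, {
    list(
      baselines = stats::rnorm(n_participants, 1.3, 0.08),
      effects = if (is.null(song_effects)) {
        stats::runif(n_songs, -0.12, 0.12)
      } else song_effects
    )
  })
  stopifnot(length(params$effects) == n_songs)
  song_ids <- sprintf("S%02d", seq_len(n_songs))
  trials <- list()
  k <- 0L
  for (p in seq_len(n_participants)) {
    pid <- sprintf("P%02d", p)
    for (m in seq_len(n_metronomes)) {
      k <- k + 1L
      trials[[k]] <- simulate_walk_trial(
        walk_spec(speed = params$baselines[p], cadence = 130,
                  radius = radius, duration = duration,
                  sample_rate = sample_rate,
                  heading_noise_sd = heading_noise_sd,
                  seed = child_seed(seed, k)),
        participant_id = pid, stimulus_id = sprintf("M%02d", m),
        stimulus_kind = "metronome")
    }
    for (s in seq_len(n_songs)) {
      k <- k + 1L
      trials[[k]] <- simulate_walk_trial(
        walk_spec(speed = params$baselines[p] * (1 + params$effects[s]),
                  cadence = 130, radius = radius, duration = duration,
                  sample_rate = sample_rate,
                  heading_noise_sd = heading_noise_sd,
                  seed = child_seed(seed, k)),
        participant_id = pid, stimulus_id = song_ids[s],
        stimulus_kind = "song")
    }
  }
  list(trials = trials, song_effects = stats::setNames(params$effects, song_ids),
       baselines = params$baselines)
}
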