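#' Pipeline run configuration
#'
#' Bundles paths, study constants and tolerances for a full pipeline run.
#' All study constants (circle radius 7.5 m, trial duration 30 s, tempo
#' 130 BPM, sensor rate 50 Hz) are configurable, not hard-coded.
#'
#' @param stimuli_dir directory of stimulus WAV files.
#' @param trials_dir directory of trial CSVs ([write_trial_csv()] layout).
#' @param out_dir output directory.
#' @param ratings_csv optional CSV of per-excerpt mean adjective ratings.
#' @param radius circle radius in m.
#' @param duration trial duration in s.
#' @param tempo stimulus tempo in BPM.
#' @param audio_sample_rate audio sampling rate in Hz.
#' @param sensor_sample_rate sensor sampling rate in Hz.
#' @param sync_tol synchronization tolerance in steps per minute.
#' @param onset_window beat-onset half-window in seconds.
#' @param n_group extreme-group size.
#' @param seed integer seed for fold assignment and simulation.
#' @return An object of class `run_config`.
#' @export
run_config <- function(stimuli_dir = "stimuli", trials_dir = "trials",
                       out_dir = "out", ratings_csv = NULL,
                       radius = 7.5, duration = 30, tempo = 130,
                       audio_sample_rate = 22050, sensor_sample_rate = 50,
                       sync_tol = 2, onset_window = 0.07, n_group = 10,
                       seed = 1) {
  cfg <- list(stimuli_dir = stimuli_dir, trials_dir = trials_dir,
              out_dir = out_dir, ratings_csv = ratings_csv,
              radius = radius, duration = duration, tempo = tempo,
              audio_sample_rate = audio_sample_rate,
              sensor_sample_rate = sensor_sample_rate,
              sync_tol = sync_tol, onset_window = onset_window,
              n_group = n_group, seed = as.integer(seed))
  stopifnot(radius > 0, duration > 0, tempo > 0, audio_sample_rate > 0,
            sensor_sample_rate > 0, sync_tol > 0, onset_window > 0)
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' The configuration round-trips losslessly through its YAML representation.
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path`; `read_config` a `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Hash of a run configuration
#'
#' MD5 of the canonical YAML form, stamped into every output file for
#' provenance.
#'
#' @param config a [run_config()].
#' @return Character MD5 digest.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

write_provenance <- function(config, path, extra = list()) {
  jsonlite::write_json(
    c(list(config_hash = config_hash(config), seed = config$seed), extra),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Extract song features for every stimulus WAV in a directory
#'
#' Reads each `.wav` in `config$stimuli_dir`, runs the full three-level
#' feature extraction and returns one 190-column row per stimulus.
#' Unreadable files are skipped with a logged message. Results and a
#' provenance sidecar are written to `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return Matrix (stimuli x 190) of song features, invisibly also written
#'   to `features.csv`.
#' @export
run_extract <- function(config) {
  t0 <- Sys.time()
  wavs <- list.files(config$stimuli_dir, pattern = "\\.wav$",
                     full.names = TRUE)
  if (length(wavs) == 0) {
    warning("no WAV files found in ", config$stimuli_dir)
    return(matrix(numeric(0), nrow = 0, ncol = 190,
                  dimnames = list(NULL, feature_registry()$name)))
  }
  rows <- list()
  for (w in wavs) {
    sid <- sub("\\.wav$", "", basename(w))
    sv <- tryCatch(
      extract_song_features(read_wav(w, nominal_tempo = config$tempo)),
      error = function(e) {
        stage_log("extract", "skipping %s: %s", basename(w),
                  conditionMessage(e))
        NULL
      })
    if (!is.null(sv)) rows[[sid]] <- sv$values
  }
  features <- do.call(rbind, rows)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(features, file.path(config$out_dir, "features.csv"))
  write_provenance(config, file.path(config$out_dir, "features.json"),
                   list(n_stimuli = nrow(features)))
  stage_log("extract", "%d stimuli in %.1f s", nrow(features),
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  features
}

#' Derive normalized per-song speeds from a directory of trial CSVs
#'
#' Reads every trial CSV in `config$trials_dir`, computes gait metrics per
#' trial, and aggregates acceptable trials into a metronome-normalized
#' per-song speed table. Unreadable files are skipped with a logged message.
#'
#' @param config a [run_config()].
#' @return A [normalize_speeds()] table, also written to `speeds.csv`.
#' @export
run_gait <- function(config) {
  t0 <- Sys.time()
  files <- list.files(config$trials_dir, pattern = "\\.csv$",
                      full.names = TRUE)
  if (length(files) == 0) stop("no trial CSVs found in ", config$trials_dir)
  trials <- list()
  for (f in files) {
    tr <- tryCatch(read_trial_csv(f), error = function(e) {
      stage_log("gait", "skipping %s: %s", basename(f), conditionMessage(e))
      NULL
    })
    if (!is.null(tr)) trials[[length(trials) + 1L]] <- tr
  }
  results <- gait_table(trials, radius = config$radius,
                        stimulus_tempo = config$tempo,
                        sync_tol = config$sync_tol)
  speeds <- normalize_speeds(results)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(results, file.path(config$out_dir, "gait_results.csv"),
                   row.names = FALSE)
  utils::write.csv(speeds, file.path(config$out_dir, "speeds.csv"),
                   row.names = FALSE)
  write_provenance(config, file.path(config$out_dir, "speeds.json"),
                   list(n_trials = nrow(results),
                        metronome_mean = attr(speeds, "metronome_mean")))
  stage_log("gait", "%d trials, %d songs in %.1f s", nrow(results),
            nrow(speeds),
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  speeds
}

#' Run the full pipeline: features, speeds, regression, group statistics
#'
#' Runs [run_extract()] and [run_gait()], joins features and speeds by
#' stimulus id, fits the nested cross-validated speed model (when at least
#' 20 songs are available; otherwise the modelling stage is skipped with a
#' notice), and computes the extreme-group statistics. Ratings statistics
#' are computed only when `config$ratings_csv` is set and readable. A JSON
#' report with the configuration hash and seed is written to
#' `config$out_dir`. Reruns with the same configuration and seed are
#' deterministic.
#'
#' @param config a [run_config()].
#' @return List with `features`, `speeds`, `cv_report` (or NULL), `model`
#'   (or NULL), `anova`, `ratings` (or NULL).
#' @export
run_all <- function(config) {
  features <- tryCatch(run_extract(config),
                       error = function(e) stop("[extract] ",
                                                conditionMessage(e)))
  speeds <- tryCatch(run_gait(config),
                     error = function(e) stop("[gait] ",
                                              conditionMessage(e)))
  common <- intersect(rownames(features), speeds$stimulus_id)
  report <- model <- NULL
  if (length(common) >= 20) {
    X <- features[common, , drop = FALSE]
    y <- stats::setNames(speeds$v, speeds$stimulus_id)[common]
    report <- tryCatch(nested_cv(X, y, seed = config$seed),
                       error = function(e) stop("[model] ",
                                                conditionMessage(e)))
    model <- final_model(X, y, report)
    write_cv_report(report, file.path(config$out_dir, "cv_report.json"))
  } else {
    stage_log("model", "skipped: %d matched songs (need >= 20)",
              length(common))
  }
  stats_out <- NULL
  if (nrow(speeds) >= 3 * config$n_group) {
    groups <- extreme_groups(speeds, n_group = config$n_group)
    stats_out <- list(groups = groups,
                      anova = speed_anova(speeds, groups))
    if (!is.null(config$ratings_csv) && file.exists(config$ratings_csv)) {
      ratings <- as.matrix(utils::read.csv(config$ratings_csv,
                                           row.names = 1))
      stats_out$ratings <- ratings_tests(ratings, groups)
    } else if (!is.null(config$ratings_csv)) {
      stage_log("stats", "ratings file missing, ratings tests skipped")
    }
  } else {
    stage_log("stats", "skipped: too few songs for extreme groups")
  }
  out <- list(features = features, speeds = speeds, cv_report = report,
              model = model, stats = stats_out)
  write_provenance(config, file.path(config$out_dir, "run_report.json"),
                   list(stages = c("extract", "gait",
                                   if (!is.null(report)) "model",
                                   if (!is.null(stats_out)) "stats")))
  out
}
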