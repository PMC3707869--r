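#' Specification of a planted sparse linear speed model
#'
#' Describes a synthetic song-by-feature table in which a known sparse subset
#' of features drives the per-song walking speed. The defaults match the
#' study's dimensions: 52 songs, 190 features, baseline speed 100 (percent of
#' metronome speed).
#'
#' @param n_songs number of songs.
#' @param true_feature_ids registry ids of the planted features.
#' @param coefficients one coefficient per planted feature.
#' @param intercept baseline speed; 100 by default.
#' @param noise_sd standard deviation of the additive Gaussian speed noise.
#' @param n_features total number of features in the table.
#' @param seed integer seed.
#' @return An object of class `planted_model_spec`.
#' @export
planted_model_spec <- function(n_songs = 52,
                               true_feature_ids = c(10, 45, 120, 178),
                               coefficients = c(6, -5, 5, -7),
                               intercept = 100, noise_sd = 1,
                               n_features = 190, seed = 1) {
  if (anyDuplicated(true_feature_ids)) {
    stop("invalid spec: true_feature_ids must be distinct")
  }
  if (any(true_feature_ids < 1) || any(true_feature_ids > n_features)) {
    stop("invalid spec: true_feature_ids must lie in the feature registry")
  }
  if (length(coefficients) != length(true_feature_ids)) {
    stop("invalid spec: one coefficient per planted feature")
  }
  if (n_songs < length(true_feature_ids) + 2) {
    stop("invalid spec: n_songs must be at least the number of planted ",
         "features plus 2")
  }
  structure(
    list(n_songs = as.integer(n_songs),
         true_feature_ids = as.integer(true_feature_ids),
         coefficients = coefficients, intercept = intercept,
         noise_sd = noise_sd, n_features = as.integer(n_features),
         seed = as.integer(seed)),
    class = "planted_model_spec"
  )
}

#' Simulate a song-by-feature table with planted linear speeds
#'
#' Non-planted features are independent standard normal noise; speeds are
#' `intercept + sum(coef_i * feature_i) + N(0, noise_sd)`. The planted
#' columns are decorrelated in-sample (centered, orthonormalized and scaled
#' to unit standard deviation), so the planted effect sizes are realized
#' exactly rather than perturbed by sampling collinearity — the planted
#' model is identifiable by construction.
#'
#' @param spec a [planted_model_spec()].
#' @return A list with `features` (matrix `n_songs x n_features`, columns
#'   `f001..`), `speeds` (numeric vector) and `spec`.
#' @export
simulate_speed_dataset <- function(spec) {
  stopifnot(inherits(spec, "planted_model_spec"))
  with_seed(spec$seed, {
    X <- matrix(stats::rnorm(spec$n_songs * spec$n_features),
                nrow = spec$n_songs)
    colnames(X) <- sprintf("f%03d", seq_len(spec$n_features))
    rownames(X) <- sprintf("S%02d", seq_len(spec$n_songs))
    planted <- spec$true_feature_ids
    Q <- qr.Q(qr(cbind(1, X[, planted, drop = FALSE])))[, -1, drop = FALSE]
    X[, planted] <- Q * sqrt(spec$n_songs - 1)
    y <- spec$intercept +
      as.numeric(X[, spec$true_feature_ids, drop = FALSE] %*% spec$coefficients)
    if (spec$noise_sd > 0) {
      y <- y + stats::rnorm(spec$n_songs, 0, spec$noise_sd)
    }
    list(features = X, speeds = stats::setNames(y, rownames(X)), spec = spec)
  })
}

#' The nine bipolar adjective pairs of the rating task
#'
#' Each pair is scored 0-100, with 0 the first adjective and 100 the second.
#'
#' @return Character vector of length 9.
#' @export
adjective_pairs <- function() {
  c("good_bad", "happy_sad", "tender_aggressive", "soft_loud", "slow_fast",
    "moving_static", "stuttering_flowing", "easy_difficult", "known_unknown")
}

#' Simulate per-excerpt mean bipolar-adjective ratings
#'
#' Plants a location shift between activating and relaxing excerpts on the
#' five adjective pairs for which the study design predicts group differences
#' (good-bad, tender-aggressive, soft-loud, slow-fast, stuttering-flowing);
#' activating excerpts shift toward bad/aggressive/loud/fast/stuttering.
#' The remaining four pairs are drawn identically in both groups.
#'
#' @param activating_ids,relaxing_ids row identifiers for the two extreme
#'   groups.
#' @param other_ids identifiers of the remaining (unshifted) excerpts.
#' @param shift total planted location shift on the 0-100 scale.
#' @param sd rating noise standard deviation.
#' @param seed integer seed.
#' @return Matrix (excerpts x 9 adjectives) of mean ratings in \[0, 100\].
#' @export
simulate_ratings <- function(activating_ids, relaxing_ids,
                             other_ids = character(0), shift = 20, sd = 8,
                             seed = 1) {
  ids <- c(activating_ids, relaxing_ids, other_ids)
  pairs <- adjective_pairs()
  shifted <- c("good_bad", "tender_aggressive", "soft_loud", "slow_fast",
               "stuttering_flowing")
  # sign: +1 means activating scores higher on the 0-100 scale.
  # stuttering_flowing has the activating pole (stuttering) at 0.
  sign <- ifelse(pairs == "stuttering_flowing", -1, 1)
  with_seed(seed, {
    m <- matrix(stats::rnorm(length(ids) * 9, 50, sd), ncol = 9,
                dimnames = list(ids, pairs))
    for (j in seq_along(pairs)) {
      if (pairs[j] %in% shifted) {
        m[activating_ids, j] <- m[activating_ids, j] + sign[j] * shift / 2
        m[relaxing_ids, j] <- m[relaxing_ids, j] - sign[j] * shift / 2
      }
    }
    pmin(pmax(m, 0), 100)
  })
}
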