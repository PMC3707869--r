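#' @keywords internal
"_PACKAGE"

# Run `code` with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  } else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  force(code)
}

# Derive a child seed from a parent seed and an index, kept inside 32-bit range.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 131 + 17) %%
               2147483629)
}

#' Root mean squared error
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
rmse <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  sqrt(mean((observed - predicted)^2))
}

#' Pearson correlation between observations and predictions
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return Correlation in \[-1, 1\].
#' @export
pcc <- function(observed, predicted) {
  stats::cor(observed, predicted)
}

# Sample skewness (third standardized moment, population form).
skewness_m3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(0)
  s <- stats::sd(x) * sqrt((n - 1) / n)
  if (s <= 0) return(0)
  mean((x - mean(x))^3) / s^3
}

# Cosine similarity with the zero-vector convention used throughout: if either
# vector has zero norm the similarity is reported as 0.
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  # clamp against floating-point overshoot so the [-1, 1] invariant holds
  min(max(sum(a * b) / (na * nb), -1), 1)
}

# Number of beat onsets whose full inter-beat interval fits inside `duration`.
# For an exact multiple (30 s at 130 BPM spans 65 beat periods) the final onset
# whose period ends exactly at the clip edge is dropped, giving the 64-onset
# convention used for the standard stimulus.
beats_in_duration <- function(duration, tempo) {
  x <- duration * tempo / 60
  n <- if (abs(x - round(x)) < 1e-9) round(x) - 1L else floor(x)
  as.integer(max(n, 0L))
}
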