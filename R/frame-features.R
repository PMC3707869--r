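#' The 52-note equal-tempered analysis grid
#'
#' Frequencies `440 * 2^(k/12)` restricted to the open interval
#' (100, 2000) Hz, i.e. `k = -25 .. 26`: 52 notes from about 103.8 Hz to
#' about 1975.5 Hz.
#'
#' @return Numeric vector of 52 strictly increasing frequencies in Hz.
#' @export
note_grid <- function() {
  k <- -60:60
  f <- 440 * 2^(k / 12)
  f[f > 100 & f < 2000]
}

#' Pitch class (chroma) of a frequency
#'
#' `round(12 * log2(f / 440)) mod 12`, so A maps to 0. Zero frequencies map
#' to chroma 0 by convention (used for absent notes).
#'
#' @param f frequency in Hz.
#' @return Integer chroma index in 0..11.
#' @export
chroma_of <- function(f) {
  ifelse(f <= 0, 0L, as.integer(round(12 * log2(f / 440)) %% 12))
}

# Octave-fold a frequency into [440, 880); 0 stays 0.
fold_to_octave <- function(f) {
  ifelse(f <= 0, 0, f * 2^(-floor(log2(f / 440))))
}

# Short-time magnitude spectrum with a Hann window. Returns frame-center
# times, the bin frequencies and a bins x frames magnitude matrix.
stft_mag <- function(x, sample_rate, frame_len, hop, max_freq = NULL) {
  nf <- round(frame_len * sample_rate)
  nh <- max(round(hop * sample_rate), 1L)
  if (length(x) < nf) stop("clip shorter than one analysis frame")
  starts <- seq(1L, length(x) - nf + 1L, by = nh)
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nf) - 1) / (nf - 1))
  nfft <- 2^ceiling(log2(nf))
  frames <- matrix(0, nrow = nfft, ncol = length(starts))
  for (i in seq_along(starts)) {
    frames[seq_len(nf), i] <- x[starts[i]:(starts[i] + nf - 1L)] * win
  }
  sp <- stats::mvfft(frames)
  freqs <- (seq_len(nfft) - 1) / nfft * sample_rate
  keep <- freqs <= if (is.null(max_freq)) sample_rate / 2 else max_freq
  list(times = (starts - 1 + nf / 2) / sample_rate,
       freqs = freqs[keep],
       mag = Mod(sp[keep, , drop = FALSE]))
}

#' Subband filter center frequencies
#' @return The six triangular-filter centers in Hz.
#' @export
subband_centers <- function() c(118, 298, 570, 983, 1609, 2559)

# Triangular filter bank on the magnitude-squared spectrum. Vertices of band
# i sit at the adjacent centers; the outer edges are extended geometrically
# by the mean adjacent center ratio.
triangular_filterbank <- function(freqs, centers = subband_centers()) {
  rbar <- exp(mean(diff(log(centers))))
  edges <- c(centers[1] / rbar, centers, centers[length(centers)] * rbar)
  W <- matrix(0, nrow = length(freqs), ncol = length(centers))
  for (i in seq_along(centers)) {
    lo <- edges[i]; ce <- edges[i + 1]; hi <- edges[i + 2]
    up <- freqs >= lo & freqs <= ce
    dn <- freqs > ce & freqs <= hi
    W[up, i] <- (freqs[up] - lo) / (ce - lo)
    W[dn, i] <- (hi - freqs[dn]) / (hi - ce)
  }
  W
}

#' Frame-level subband loudness
#'
#' Decomposes the clip into 30 ms frames shifted by 5 ms, measures the energy
#' in six triangular frequency bands (centers 118, 298, 570, 983, 1609 and
#' 2559 Hz) per frame, and maps energies to loudness as `energy^0.25`. The
#' total loudness is the fourth root of the summed band energies.
#'
#' @param clip an [audio_clip()].
#' @param frame_len,hop frame length and hop in seconds.
#' @return An object of class `loudness_series`: frame times plus a
#'   frames x 7 loudness matrix with columns `total, band1..band6`.
#' @export
subband_loudness <- function(clip, frame_len = 0.030, hop = 0.005) {
  s <- stft_mag(clip$samples, clip$sample_rate, frame_len, hop)
  W <- triangular_filterbank(s$freqs)
  energy <- t(W) %*% s$mag^2                 # 6 x frames
  loud <- cbind(total = colSums(energy)^0.25, t(energy)^0.25)
  colnames(loud) <- c("total", paste0("band", 1:6))
  structure(
    list(frame_times = s$times, loudness = loud,
         frame_len = frame_len, hop = hop),
    class = "loudness_series"
  )
}

#' Frame-level note-evidence (pitch salience) series
#'
#' Uses 150 ms frames shifted by 20 ms. The salience of a grid note is the
#' harmonic sum of spectral magnitudes: the maximum magnitude within one
#' quarter-tone of the fundamental plus half the maxima around harmonics 2
#' and 3. A fundamental gate zeroes the salience of notes whose fundamental
#' magnitude falls below `gate` times the strongest grid fundamental in the
#' frame, preventing subharmonic attribution.
#'
#' @param clip an [audio_clip()].
#' @param frame_len,hop frame length and hop in seconds.
#' @param gate relative fundamental gate in \[0, 1).
#' @return An object of class `note_evidence_series`: frame times, a
#'   frames x 52 evidence matrix and the note grid.
#' @export
note_evidence <- function(clip, frame_len = 0.150, hop = 0.020, gate = 0.1) {
  grid <- note_grid()
  qt <- 2^(1 / 24)
  s <- stft_mag(clip$samples, clip$sample_rate, frame_len, hop,
                max_freq = min(3 * max(grid) * qt * 1.01,
                               clip$sample_rate / 2))
  nfr <- ncol(s$mag)
  band_max <- function(lo, hi) {
    rows <- which(s$freqs >= lo & s$freqs <= hi)
    if (length(rows) == 0L) return(numeric(nfr))
    if (length(rows) == 1L) return(s$mag[rows, ])
    do.call(pmax, lapply(rows, function(r) s$mag[r, ]))
  }
  fund <- vapply(grid, function(f) band_max(f / qt, f * qt), numeric(nfr))
  h2 <- vapply(grid, function(f) band_max(2 * f / qt, 2 * f * qt),
               numeric(nfr))
  h3 <- vapply(grid, function(f) band_max(3 * f / qt, 3 * f * qt),
               numeric(nfr))
  sal <- fund + 0.5 * h2 + 0.5 * h3
  frame_peak <- apply(fund, 1, max)
  sal[fund < gate * frame_peak] <- 0
  colnames(sal) <- sprintf("note%02d", seq_along(grid))
  structure(
    list(frame_times = s$times, evidence = sal, note_grid = grid,
         frame_len = frame_len, hop = hop),
    class = "note_evidence_series"
  )
}
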