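#' Audio clip container
#'
#' A mono waveform with its sample rate and, optionally, the nominal tempo of
#' the stimulus it encodes. All analysis functions in the package operate on
#' this container; stereo material is mixed down to mono on read.
#'
#' @param samples numeric vector of amplitudes (nominally in \[-1, 1\]).
#' @param sample_rate sampling frequency in Hz.
#' @param nominal_tempo optional stimulus tempo in beats per minute.
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, sample_rate, nominal_tempo = NULL) {
  stopifnot(is.numeric(samples), length(sample_rate) == 1L, sample_rate > 0)
  structure(
    list(samples = as.numeric(samples),
         sample_rate = as.numeric(sample_rate),
         nominal_tempo = nominal_tempo),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %.3f s at %g Hz%s\n",
              clip_duration(x), x$sample_rate,
              if (is.null(x$nominal_tempo)) "" else
                sprintf(", nominal tempo %g BPM", x$nominal_tempo)))
  invisible(x)
}

#' Duration of an audio clip in seconds
#' @param clip an [audio_clip()].
#' @export
clip_duration <- function(clip) {
  length(clip$samples) / clip$sample_rate
}

#' Write an audio clip to a WAV file
#'
#' Writes a mono RIFF/WAVE file, either 16-bit PCM or 32-bit IEEE float.
#'
#' @param clip an [audio_clip()].
#' @param path output file path.
#' @param format `"pcm16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  x <- clip$samples
  sr <- as.integer(round(clip$sample_rate))
  n <- length(x)
  bits <- if (format == "pcm16") 16L else 32L
  bytes_per_sample <- bits %/% 8L
  data_size <- n * bytes_per_sample
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  audio_format <- if (format == "pcm16") 1L else 3L
  writeBin(audio_format, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * bytes_per_sample, con, size = 4, endian = "little")
  writeBin(bytes_per_sample, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "pcm16") {
    q <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file into an audio clip
#'
#' Supports 16-bit PCM and 32-bit float RIFF/WAVE files, mono or stereo.
#' Stereo material is mixed to mono by channel averaging, since all feature
#' definitions are single-channel.
#'
#' @param path path to a `.wav` file.
#' @param nominal_tempo optional tempo metadata to attach, in BPM.
#' @return An [audio_clip()].
#' @export
read_wav <- function(path, nominal_tempo = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)
  audio_format <- NA_integer_; n_channels <- NA_integer_
  sr <- NA_integer_; bits <- NA_integer_; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      audio_format <- readBin(con, integer(), size = 2, endian = "little")
      n_channels <- readBin(con, integer(), size = 2, endian = "little")
      sr <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16L) readBin(con, raw(), n = size - 16L)
    } else if (identical(id, "data")) {
      if (is.na(audio_format)) stop("malformed WAV: data before fmt chunk")
      if (audio_format == 1L && bits == 16L) {
        samples <- readBin(con, integer(), n = size %/% 2L, size = 2,
                           signed = TRUE, endian = "little") / 32767
      } else if (audio_format == 3L && bits == 32L) {
        samples <- readBin(con, numeric(), n = size %/% 4L, size = 4,
                           endian = "little")
      } else {
        stop("unsupported WAV encoding (format ", audio_format,
             ", ", bits, " bit)")
      }
      break
    } else {
      readBin(con, raw(), n = size + (size %% 2L))
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (n_channels > 1L) {
    samples <- colMeans(matrix(samples, nrow = n_channels))
  }
  audio_clip(samples, sr, nominal_tempo = nominal_tempo)
}
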