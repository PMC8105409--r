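#' Construct an audio clip
#'
#' Light container for a mono PCM waveform. Samples are dimensionless in
#' \code{[-1, 1]}; the sample rate must be at least 22.05 kHz, the minimum
#' used for zebra finch song analysis (song energy extends to ~8.6 kHz).
#'
#' @param samples Numeric vector of mono samples, all finite.
#' @param sample_rate Sampling rate in Hz (>= 22050).
#' @return An object of class \code{audio_clip} with elements \code{samples}
#'   and \code{sample_rate}.
#' @export
audio_clip <- function(samples, sample_rate) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("audio clip has zero duration")
  if (!all(is.finite(samples))) stop("non-finite samples in audio clip")
  sample_rate <- as.numeric(sample_rate)
  if (length(sample_rate) != 1L || !is.finite(sample_rate) || sample_rate < 22050)
    stop("sample_rate must be a single value >= 22050 Hz")
  structure(list(samples = samples, sample_rate = sample_rate),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip: %.3f s @ %g Hz>\n",
              length(x$samples) / x$sample_rate, x$sample_rate))
  invisible(x)
}

#' Duration of an audio clip in seconds
#' @param clip An \code{audio_clip}.
#' @return Duration in seconds.
#' @export
clip_duration <- function(clip) {
  stopifnot(inherits(clip, "audio_clip"))
  length(clip$samples) / clip$sample_rate
}

#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed mono audio: integer PCM
#' (16/24/32 bit) or IEEE float32. Stereo and compressed formats are
#' rejected. Samples are rescaled to \code{[-1, 1]}.
#'
#' @param path Path to a WAV file.
#' @return An \code{audio_clip}.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        format   = readBin(body[1:2], "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(body[3:4], "integer", 1, 2, endian = "little", signed = FALSE),
        rate     = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits     = readBin(body[15:16], "integer", 1, 2, endian = "little", signed = FALSE))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + (size %% 2L)))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV (missing fmt/data chunk): ", path)
  if (fmt$channels != 1L) stop("stereo or multi-channel WAV not supported: ", path)

  if (fmt$format == 1L) {          # integer PCM
    if (fmt$bits == 16L) {
      x <- readBin(data_raw, "integer", length(data_raw) %/% 2L, 2, signed = TRUE,
                   endian = "little") / 32767
    } else if (fmt$bits == 24L) {
      n <- length(data_raw) %/% 3L
      b <- matrix(as.integer(data_raw[seq_len(3L * n)]), nrow = 3L)
      v <- b[1L, ] + 256L * b[2L, ] + 65536L * b[3L, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      x <- v / 8388607
    } else if (fmt$bits == 32L) {
      x <- readBin(data_raw, "integer", length(data_raw) %/% 4L, 4,
                   endian = "little") / 2147483647
    } else stop("unsupported PCM bit depth: ", fmt$bits)
  } else if (fmt$format == 3L) {   # IEEE float
    if (fmt$bits != 32L) stop("unsupported float bit depth: ", fmt$bits)
    x <- readBin(data_raw, "double", length(data_raw) %/% 4L, 4, endian = "little")
  } else stop("unsupported WAV format code: ", fmt$format)

  audio_clip(x, fmt$rate)
}

#' Write a mono WAV file (16-bit PCM)
#'
#' @param clip An \code{audio_clip}; samples are clipped to \code{[-1, 1]}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- pmax(-1, pmin(1, clip$samples))
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 1L), con, 2, endian = "little")              # PCM, mono
  writeBin(as.integer(clip$sample_rate), con, 4, endian = "little")
  writeBin(as.integer(clip$sample_rate * 2), con, 4, endian = "little")
  writeBin(c(2L, 16L), con, 2, endian = "little")             # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
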