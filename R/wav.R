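#' Audio signal container
#'
#' @param samples numeric vector of amplitudes on the full-scale range
#'   `[-1, 1]`.
#' @param sample_rate sampling rate in Hz.
#' @return an `audio_signal` object (list with `samples`, `sample_rate`).
#' @export
audio_signal <- function(samples, sample_rate) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("audio signal is empty")
  if (!all(is.finite(samples))) stop("audio signal contains non-finite values")
  stopifnot(sample_rate > 0)
  structure(list(samples = samples, sample_rate = sample_rate),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("audio_signal: %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' Read a PCM WAV file
#'
#' Supports 16/24/32-bit integer PCM. Stereo files are downmixed to mono
#' with a warning.
#'
#' @param path file path.
#' @return an [audio_signal()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) stop("malformed WAV: ", path)
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        sample_rate = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little"))
    } else if (id == "data") {
      if (is.null(fmt)) stop("WAV data chunk before fmt chunk: ", path)
      if (!fmt$audio_format %in% c(1L)) stop("only PCM WAV supported")
      bytes <- fmt$bits / 8
      n <- size / bytes
      if (fmt$bits == 16) {
        x <- readBin(con, "integer", n, 2, signed = TRUE, endian = "little")
        x <- x / 32768
      } else if (fmt$bits == 24) {
        raw <- readBin(con, "raw", size)
        m <- matrix(as.integer(raw), nrow = 3)
        v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        x <- v / 8388608
      } else if (fmt$bits == 32) {
        x <- readBin(con, "integer", n, 4, signed = TRUE, endian = "little")
        x <- x / 2147483648
      } else stop("unsupported PCM bit depth: ", fmt$bits)
      if (fmt$channels > 1) {
        warning("downmixing ", fmt$channels, "-channel WAV to mono")
        x <- colMeans(matrix(x, nrow = fmt$channels))
      }
      return(audio_signal(x, fmt$sample_rate))
    } else {
      readBin(con, "raw", size + size %% 2)  # skip unknown chunk (word align)
    }
  }
}

#' Write a 16-bit PCM WAV file
#'
#' @param signal an [audio_signal()]; samples outside `[-1, 1]` are clipped
#'   with a warning.
#' @param path output path.
#' @param sidecar_json optional path: when the signal carries synthesis
#'   ground truth (see [synthesize_vowel()]), write it alongside as JSON.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, sidecar_json = NULL) {
  stopifnot(inherits(signal, "audio_signal"))
  x <- signal$samples
  if (any(abs(x) > 1)) {
    warning("clipping samples outside full scale")
    x <- pmin(1, pmax(-1, x))
  }
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")              # PCM
  writeBin(1L, con, 2, endian = "little")              # mono
  writeBin(as.integer(signal$sample_rate), con, 4, endian = "little")
  writeBin(as.integer(signal$sample_rate * 2), con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")              # block align
  writeBin(16L, con, 2, endian = "little")             # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  gt <- attr(signal, "ground_truth")
  if (!is.null(sidecar_json) && !is.null(gt)) {
    gt$params <- unclass(gt$params)
    jsonlite::write_json(gt, sidecar_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
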