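# Minimal RIFF/WAVE reader and writer.
# Accepted dialects: PCM 16-bit, PCM 32-bit, IEEE float 32-bit, mono or
# multichannel (averaged to mono on read). Extensible-format headers
# (wFormatTag 0xFFFE) are resolved through the SubFormat GUID.

#' Read a WAV file as a mono audio signal
#'
#' Multichannel files are averaged to mono (the acquisition device is a
#' single microphone; channel averaging is the least surprising reduction).
#' Integer PCM samples are scaled to `[-1, 1]`.
#'
#' @param path path to a RIFF/WAVE file (PCM16, PCM32 or float32).
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4) stop("malformed WAV (no data chunk): ", path)
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      if (sz %% 2 == 1) readBin(con, "raw", 1)
      fmt <- list(
        tag       = readBin(raw[1:2], "integer", 1, size = 2, signed = FALSE, endian = "little"),
        channels  = readBin(raw[3:4], "integer", 1, size = 2, signed = FALSE, endian = "little"),
        rate      = readBin(raw[5:8], "integer", 1, size = 4, endian = "little"),
        bits      = readBin(raw[15:16], "integer", 1, size = 2, signed = FALSE, endian = "little")
      )
      if (fmt$tag == 0xFFFE && sz >= 40) {
        # extensible: first two bytes of the SubFormat GUID carry the real tag
        fmt$tag <- readBin(raw[25:26], "integer", 1, size = 2, signed = FALSE, endian = "little")
      }
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV (data before fmt): ", path)
      x <- read_wav_data(con, sz, fmt, path)
      if (fmt$channels > 1L) {
        nfr <- length(x) %/% fmt$channels
        x <- colMeans(matrix(x[seq_len(nfr * fmt$channels)], nrow = fmt$channels))
      }
      return(audio_signal(x, fmt$rate))
    } else {
      seek(con, sz + sz %% 2, origin = "current")
    }
  }
}

read_wav_data <- function(con, sz, fmt, path) {
  if (fmt$tag == 1L) {         # integer PCM
    if (fmt$bits == 16L) {
      readBin(con, "integer", sz %/% 2, size = 2, signed = TRUE,
              endian = "little") / 32768
    } else if (fmt$bits == 32L) {
      readBin(con, "integer", sz %/% 4, size = 4, endian = "little") / 2147483648
    } else {
      stop("unsupported PCM bit depth (", fmt$bits, "): ", path)
    }
  } else if (fmt$tag == 3L) {  # IEEE float
    if (fmt$bits != 32L) stop("unsupported float bit depth (", fmt$bits, "): ", path)
    readBin(con, "double", sz %/% 4, size = 4, endian = "little")
  } else {
    stop("unsupported WAV format tag (", fmt$tag, "): ", path)
  }
}

#' Write an audio signal to a WAV file
#'
#' @param signal an [audio_signal()]; samples outside `[-1, 1]` are clipped
#'   for integer encodings.
#' @param path output path.
#' @param format one of `"pcm16"` (default) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, format = c("pcm16", "float32")) {
  stopifnot(inherits(signal, "audio_signal"))
  format <- match.arg(format)
  x <- signal$samples
  fs <- as.integer(round(signal$sample_rate))
  bytes_per <- if (format == "pcm16") 2L else 4L
  data_sz <- length(x) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_sz), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  tag <- if (format == "pcm16") 1L else 3L
  writeBin(tag, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")   # block align
  writeBin(8L * bytes_per, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, size = 4, endian = "little")
  if (format == "pcm16") {
    # scale by 32768 (the read-side divisor) so write/read is a fixed
    # point on the 16-bit grid; clip the one unrepresentable top code
    q <- as.integer(pmin(32767, pmax(-32768, round(x * 32768))))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}
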