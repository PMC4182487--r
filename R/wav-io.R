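#' Write a waveform to a WAV file (32-bit float PCM)
#'
#' Writes mono (numeric vector) or multi-channel (one column per channel)
#' audio as an IEEE-float RIFF/WAVE file. Samples are written as-is; values
#' outside \[-1, 1\] are preserved (float WAV has no hard clip), so normalise
#' before writing if a player expects full-scale audio.
#'
#' @param wave numeric vector (mono) or matrix with one column per channel.
#' @param fs sampling rate in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_wav()]
#' @export
write_wav <- function(wave, fs, path) {
  if (is.vector(wave)) wave <- matrix(wave, ncol = 1L)
  if (!is.matrix(wave) || !is.numeric(wave)) {
    stop("`wave` must be a numeric vector or matrix", call. = FALSE)
  }
  stopifnot_scalar(fs)
  n_chan <- ncol(wave)
  n_samp <- nrow(wave)
  block_align <- 4L * n_chan
  data_bytes <- block_align * n_samp
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  # riff size: 4 ("WAVE") + (8+16) fmt + (8+4) fact + 8 + data
  w(as.integer(4 + 24 + 12 + 8 + data_bytes), 4L)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w(16L, 4L)
  w(3L, 2L)                       # format 3 = IEEE float
  w(n_chan, 2L)
  w(as.integer(fs), 4L)
  w(as.integer(fs * block_align), 4L)
  w(block_align, 2L)
  w(32L, 2L)
  writeChar("fact", con, eos = NULL)
  w(4L, 4L)
  w(n_samp, 4L)
  writeChar("data", con, eos = NULL)
  w(data_bytes, 4L)
  # interleave channels
  writeBin(as.numeric(t(wave)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a WAV file
#'
#' Reads IEEE-float (32-bit) or integer PCM (16-bit) RIFF/WAVE files, the two
#' encodings this package and common audio tools exchange. Integer samples
#' are rescaled to \[-1, 1).
#'
#' @param path input file path.
#' @return list with `wave` (matrix, one column per channel) and `fs` (Hz).
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  r <- function(size, n = 1L, what = "integer", signed = TRUE) {
    readBin(con, what, n = n, size = size, endian = "little", signed = signed)
  }
  if (!identical(readChar(con, 4L), "RIFF")) stop("not a RIFF file", call. = FALSE)
  r(4L)
  if (!identical(readChar(con, 4L), "WAVE")) stop("not a WAVE file", call. = FALSE)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4L)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk found", call. = FALSE)
    size <- r(4L)
    if (identical(id, "fmt ")) {
      fmt <- list(
        format = r(2L), channels = r(2L), fs = r(4L),
        byte_rate = r(4L), block_align = r(2L), bits = r(2L)
      )
      if (size > 16L) r(1L, n = size - 16L, signed = FALSE)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("data chunk before fmt chunk", call. = FALSE)
      n_val <- size %/% (fmt$bits %/% 8L)
      raw_vals <- if (fmt$format == 3L && fmt$bits == 32L) {
        readBin(con, "numeric", n = n_val, size = 4L, endian = "little")
      } else if (fmt$format == 1L && fmt$bits == 16L) {
        r(2L, n = n_val) / 32768
      } else {
        stop("unsupported WAV encoding (need float32 or int16 PCM)", call. = FALSE)
      }
      wave <- matrix(raw_vals, ncol = fmt$channels, byrow = TRUE)
      return(list(wave = wave, fs = fmt$fs))
    } else {
      r(1L, n = size + size %% 2L, signed = FALSE)  # skip (chunks are word-aligned)
    }
  }
}
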