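#' Write a waveform to a mono RIFF/PCM WAV file
#'
#' Writes 16-bit little-endian PCM, the format used throughout this package.
#' Samples are expected on the \[-1, 1\] full-scale range; values outside are
#' clipped with a warning.
#'
#' @param waveform numeric vector of samples in \[-1, 1\].
#' @param path output file path.
#' @param sample_rate sampling rate in Hz.
#' @param bit_depth bits per sample; only 16 is supported.
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, path, sample_rate = 44100L, bit_depth = 16L) {
  if (bit_depth != 16L) stop("only 16-bit PCM output is supported")
  if (!is.numeric(waveform) || length(waveform) == 0L)
    stop("waveform must be a nonempty numeric vector")
  if (any(abs(waveform) > 1)) {
    warning("samples outside [-1, 1] clipped before quantisation")
    waveform <- pmin(1, pmax(-1, waveform))
  }
  pcm <- as.integer(round(waveform * 32767))
  n <- length(pcm)
  data_bytes <- 2L * n
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")           # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono RIFF/PCM WAV file
#'
#' Supports the 16-bit mono PCM files produced by [write_wav()]. Samples are
#' returned rescaled to \[-1, 1\].
#'
#' @param path WAV file path.
#' @return list with `waveform` (numeric) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file: ", path)
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk found in ", path)
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV is supported")
      if (fmt[2] != 1L) stop("only mono WAV is supported")
      sample_rate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")  # byte rate
      readBin(con, "integer", size = 2, endian = "little")  # block align
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (bits != 16L) stop("only 16-bit WAV is supported")
      if (size > 16L) readBin(con, "raw", n = size - 16L)
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", n = size %/% 2L, size = 2,
                     endian = "little", signed = TRUE)
      if (is.null(sample_rate)) stop("data chunk precedes fmt chunk in ", path)
      return(list(waveform = pcm / 32767, sample_rate = sample_rate))
    } else {
      readBin(con, "raw", n = size + (size %% 2L))
    }
  }
}
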