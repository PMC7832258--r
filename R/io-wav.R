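# Minimal 16-bit PCM RIFF/WAVE reader and writer (little-endian).

#' Read and write 16-bit PCM WAV files
#'
#' `write_wav()` stores a numeric sample matrix (one column per channel,
#' values in \[-1, 1\]) as canonical 16-bit PCM; `read_wav()` reads it back,
#' returning samples rescaled to \[-1, 1\]. Only uncompressed 16-bit PCM is
#' supported, which is what the simulator emits.
#'
#' @param samples Numeric matrix (frames x channels) or vector, in
#'   \[-1, 1\].
#' @param path File path.
#' @param sample_rate Sampling rate, Hz.
#' @return `read_wav()`: a list with `samples` (matrix, frames x channels)
#'   and `sample_rate`. `write_wav()`: the path, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  if (max(abs(samples)) > 1 + 1e-9) {
    abort_dv("WAV samples must lie within [-1, 1].", "format")
  }
  n_ch <- ncol(samples)
  pcm <- as.integer(round(pmin(pmax(t(samples), -1), 1) * 32767))
  data_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * n_ch * 2L), con, size = 4, endian = "little")
  writeBin(as.integer(n_ch * 2L), con, size = 2, endian = "little")  # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    abort_dv("Not a RIFF/WAVE file.", "format")
  }
  sample_rate <- NULL
  n_ch <- NULL
  bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) {
      abort_dv("WAV file ended before a data chunk.", "format")
    }
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) abort_dv("Only PCM WAV is supported.", "format")
      n_ch <- fmt[2]
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little") # byte rate
      readBin(con, integer(), size = 2, endian = "little") # block align
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (bits != 16L) abort_dv("Only 16-bit PCM WAV is supported.", "format")
      if (size > 16) readBin(con, raw(), n = size - 16L)
    } else if (id == "data") {
      pcm <- readBin(con, integer(), n = size / 2L, size = 2, signed = TRUE,
                     endian = "little")
      break
    } else {
      readBin(con, raw(), n = size)
    }
  }
  samples <- t(matrix(pcm / 32767, nrow = n_ch))
  list(samples = samples, sample_rate = sample_rate)
}
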