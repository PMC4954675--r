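# Minimal RIFF/WAVE PCM 16-bit mono I/O. No WAV-capable package ships with
# the target library set, so the two functions below implement the canonical
# chunk layout directly with readBin/writeBin.

#' Write a mono PCM-16 WAV file
#'
#' @param samples Numeric vector in \[-1, 1\].
#' @param path Output file path.
#' @param sample_rate Sample rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate = 16000) {
  if (any(!is.finite(samples))) data_error("samples contain non-finite values")
  pcm <- as.integer(round(pmin(pmax(samples, -1), 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")           # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono PCM-16 WAV file
#'
#' @param path Input file path.
#' @return A list with `samples` (numeric in \[-1, 1\]) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    data_error(sprintf("'%s' is not a RIFF/WAVE file", path))
  }
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) {
      data_error(sprintf("no data chunk found in '%s'", path))
    }
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      ba_bits <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L || ba_bits[2] != 16L) {
        data_error("only PCM 16-bit mono WAV files are supported")
      }
      if (sz > 16) readBin(con, raw(), n = sz - 16)
    } else if (identical(id, "data")) {
      pcm <- readBin(con, integer(), n = sz / 2, size = 2, endian = "little",
                     signed = TRUE)
      break
    } else {
      readBin(con, raw(), n = sz + sz %% 2)
    }
  }
  if (is.null(sample_rate)) data_error("fmt chunk missing before data chunk")
  list(samples = pcm / 32767, sample_rate = sample_rate)
}
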