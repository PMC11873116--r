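# Minimal RIFF/WAVE PCM16 mono reader/writer. Only the subset of the
# format this pipeline produces and consumes is supported; anything else
# is rejected loudly rather than guessed at.

#' Read a mono 16-bit PCM WAV file
#'
#' @param path path to a RIFF/WAVE file, PCM encoding, mono, 16-bit.
#' @return A [Waveform-class] with samples rescaled to `[-1, 1]`
#'   (divided by 32768).
#' @seealso [writeWav()]
#' @export
readWav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 44) stop("not a WAV file (too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fs <- NULL; n_channels <- NULL; bits <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    len <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2L, size = 2L, endian = "little", signed = FALSE)
      if (fmt[1L] != 1L) stop("unsupported WAV encoding (not PCM): ", path)
      n_channels <- fmt[2L]
      fs <- readBin(con, "integer", 1L, size = 4L, endian = "little")
      invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
      invisible(readBin(con, "integer", 1L, size = 2L, endian = "little"))
      bits <- readBin(con, "integer", 1L, size = 2L, endian = "little")
      extra <- len - 16L
      if (extra > 0L) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      if (len <= 0L) stop("empty data chunk in WAV file: ", path)
      dat <- readBin(con, "integer", len / 2L, size = 2L, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", len + len %% 2L))
    }
  }
  if (is.null(fs) || is.null(dat)) stop("malformed WAV file: ", path)
  if (n_channels != 1L) stop("only mono WAV is supported (file has ",
                             n_channels, " channels)")
  if (bits != 16L) stop("only 16-bit PCM is supported (file has ", bits, " bits)")
  waveform(dat / 32768, fs, provenance = basename(path))
}

#' Write a Waveform as a mono 16-bit PCM WAV file
#'
#' Samples are quantized by round-to-nearest to 16 bits (no dither), so
#' `readWav(writeWav(w))` preserves samples to within `2^-15` and writing
#' the same Waveform twice is bit-identical.
#'
#' @param w a [Waveform-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeWav <- function(w, path) {
  stopifnot(is(w, "Waveform"))
  x <- pmin(pmax(round(w@samples * 32768), -32768), 32767)
  n <- length(x)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")     # PCM
  writeBin(1L, con, size = 2L, endian = "little")     # mono
  writeBin(as.integer(round(w@fs)), con, size = 4L, endian = "little")
  writeBin(as.integer(round(w@fs) * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")     # block align
  writeBin(16L, con, size = 2L, endian = "little")    # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, size = 4L, endian = "little")
  writeBin(as.integer(x), con, size = 2L, endian = "little")
  invisible(path)
}
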