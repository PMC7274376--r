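# Minimal RIFF/WAVE PCM I/O. Hand-rolled because no audio package is
# available in the supported dependency set; only integer PCM written by
# this package needs to round-trip.

#' Write a waveform to a PCM WAV file
#'
#' Writes mono integer PCM (RIFF/WAVE). Samples must already lie in
#' `[-1, 1]`; amplitudes outside that range are rejected rather than
#' clipped. Round-trip through [read_audio()] reproduces samples to
#' quantization precision (`2^-(bits-1)`).
#'
#' @param waveform Numeric vector in `[-1, 1]` (as produced by
#'   [render_sequence()]), or a `narrowband_sound`/`quintet` object.
#' @param path Output file path.
#' @param sample_rate Sampling rate in Hz; taken from the object when
#'   available.
#' @param bit_depth 16 (default) or 8 bits per sample.
#' @return `path`, invisibly.
#' @export
write_audio <- function(waveform, path, sample_rate = 44100, bit_depth = 16) {
  if (inherits(waveform, c("narrowband_sound", "quintet"))) {
    sample_rate <- waveform$carrier$sample_rate
    bit_depth <- waveform$carrier$bit_depth
    waveform <- waveform$samples
  }
  if (!is.null(attr(waveform, "sample_rate")))
    sample_rate <- attr(waveform, "sample_rate")
  if (!is.numeric(waveform)) stop("`waveform` must be numeric", call. = FALSE)
  if (max(abs(waveform)) > 1)
    stop("waveform amplitude exceeds 1; normalize before writing", call. = FALSE)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16", call. = FALSE)
  n <- length(waveform)
  bytes_per <- bit_depth / 8L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36 + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16)
  w16(1); w16(1)                       # PCM, mono
  w32(sample_rate); w32(sample_rate * bytes_per)
  w16(bytes_per); w16(bit_depth)
  writeChar("data", con, eos = NULL); w32(data_size)
  if (bit_depth == 16L) {
    pcm <- as.integer(round(pmax(pmin(waveform, 1), -1) * 32767))
    writeBin(pcm, con, size = 2, endian = "little")
  } else {
    pcm <- as.integer(round((pmax(pmin(waveform, 1), -1) + 1) / 2 * 255))
    writeBin(pcm, con, size = 1)
  }
  invisible(path)
}

#' Read a PCM WAV file
#'
#' Counterpart of [write_audio()]; reads mono or multichannel integer PCM
#' and rescales to `[-1, 1]`.
#'
#' @param path WAV file path.
#' @return List with `samples` (numeric, channels interleaved dropped to
#'   mono by averaging), `sample_rate` and `bit_depth`.
#' @export
read_audio <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  r32 <- function() readBin(con, "integer", size = 4, endian = "little")
  r16 <- function() readBin(con, "integer", size = 2, endian = "little")
  tag <- readChar(con, 4)
  if (!identical(tag, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  r32()
  if (!identical(readChar(con, 4), "WAVE"))
    stop("not a WAVE file: ", path, call. = FALSE)
  sample_rate <- NULL; bit_depth <- NULL; n_channels <- 1L; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- r32()
    if (identical(id, "fmt ")) {
      r16(); n_channels <- r16()
      sample_rate <- r32(); r32(); r16()
      bit_depth <- r16()
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (identical(id, "data")) {
      if (bit_depth == 16L) {
        samples <- readBin(con, "integer", n = size / 2, size = 2,
                           endian = "little") / 32767
      } else {
        samples <- (readBin(con, "integer", n = size, size = 1,
                            signed = FALSE) / 255) * 2 - 1
      }
      break
    } else {
      readBin(con, "raw", size)
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path, call. = FALSE)
  if (n_channels > 1L) {
    samples <- colMeans(matrix(samples, nrow = n_channels))
  }
  list(samples = samples, sample_rate = sample_rate, bit_depth = bit_depth)
}
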