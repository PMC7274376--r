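#' Narrowband carrier specification
#'
#' Describes one of the study's narrowband carriers: a summation of
#' `n_components` sinusoids spanning a passband of `erb_multiplier`
#' equivalent rectangular bandwidths (ERBs) centred on `center_freq`.
#' The study used carriers at 200, 1100 and 3100 Hz with a 4-ERB band of
#' 21 components, rendered at 44.1 kHz / 16 bit.
#'
#' @param center_freq Carrier centre frequency in Hz (> 0).
#' @param erb_multiplier Passband width in ERB units (default 4).
#' @param n_components Number of summed sinusoids (default 21).
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @param bit_depth PCM bit depth for audio output (default 16).
#' @param gain Linear amplitude multiplier applied after peak
#'   normalization; stands in for the study's per-carrier perceived
#'   loudness adjustment (default 1).
#' @return An object of class `carrier_spec`.
#' @examples
#' carrier_spec(1100)
#' @export
carrier_spec <- function(center_freq, erb_multiplier = 4, n_components = 21,
                         sample_rate = 44100, bit_depth = 16, gain = 1.0) {
  if (!is.numeric(center_freq) || length(center_freq) != 1L || center_freq <= 0)
    stop("`center_freq` must be a single positive number (Hz)", call. = FALSE)
  if (n_components < 1L) stop("`n_components` must be >= 1", call. = FALSE)
  if (gain < 0 || gain > 1) stop("`gain` must lie in [0, 1]", call. = FALSE)
  bw <- erb_bandwidth(center_freq, erb_multiplier)
  if (center_freq - bw / 2 <= 0)
    stop("passband lower edge ", round(center_freq - bw / 2, 1),
         " Hz is not positive; reduce `erb_multiplier`", call. = FALSE)
  structure(
    list(center_freq = center_freq, erb_multiplier = erb_multiplier,
         n_components = as.integer(n_components), sample_rate = sample_rate,
         bit_depth = as.integer(bit_depth), gain = gain, bandwidth = bw),
    class = "carrier_spec")
}

#' @export
print.carrier_spec <- function(x, ...) {
  cat(sprintf("<carrier_spec> %g Hz, %g-ERB band = %.1f Hz (%d components), %g Hz fs\n",
              x$center_freq, x$erb_multiplier, x$bandwidth, x$n_components,
              x$sample_rate))
  invisible(x)
}

#' Equivalent rectangular bandwidth of the passband
#'
#' Glasberg & Moore ERB formula, `ERB(f) = 24.7 (4.37 f/1000 + 1)` Hz,
#' scaled by `erb_multiplier`. The passband of a carrier spans
#' `center_freq +/- erb_bandwidth(...)/2`.
#'
#' @param center_freq Centre frequency in Hz (> 0).
#' @param erb_multiplier Number of ERBs (>= 0).
#' @return Bandwidth in Hz.
#' @examples
#' erb_bandwidth(1100, 4)  # ~573.7 Hz
#' @export
erb_bandwidth <- function(center_freq, erb_multiplier = 4) {
  if (!is.numeric(center_freq) || any(center_freq <= 0))
    stop("`center_freq` must be positive (Hz)", call. = FALSE)
  if (any(erb_multiplier < 0))
    stop("`erb_multiplier` must be >= 0", call. = FALSE)
  erb_multiplier * 24.7 * (4.37 * center_freq / 1000 + 1)
}

#' Synthesize a narrowband sound
#'
#' Sums `n_components` unit-amplitude sinusoids, linearly spaced across the
#' carrier's ERB passband (edges inclusive), each with an independent
#' uniform random onset phase. The summed waveform is peak-normalized to 1,
#' optionally gated with raised-cosine onset/offset ramps, then scaled by
#' the carrier's `gain`.
#'
#' @param carrier A [carrier_spec()].
#' @param duration_ms Sound duration in ms (default 10, the study value).
#' @param ramp_ms Raised-cosine ramp duration in ms applied at onset and
#'   offset (default 1; 0 disables gating).
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   waveforms.
#' @return An object of class `narrowband_sound` with elements `samples`,
#'   `duration_ms`, `carrier` and `component_phases`.
#' @export
synth_narrowband <- function(carrier, duration_ms = 10, ramp_ms = 1,
                             seed = NULL) {
  stopifnot(inherits(carrier, "carrier_spec"))
  if (duration_ms <= 0) stop("`duration_ms` must be > 0", call. = FALSE)
  fs <- carrier$sample_rate
  n <- round(duration_ms / 1000 * fs)
  lo <- carrier$center_freq - carrier$bandwidth / 2
  hi <- carrier$center_freq + carrier$bandwidth / 2
  if (lo <= 0) stop("passband extends below 0 Hz", call. = FALSE)
  freqs <- if (carrier$n_components == 1L) carrier$center_freq else
    seq(lo, hi, length.out = carrier$n_components)
  with_seed(seed, {
    phases <- runif(carrier$n_components, 0, 2 * pi)
    t <- (seq_len(n) - 1) / fs
    # outer() keeps this a single BLAS-friendly matrix product
    x <- as.vector(sin(outer(t, 2 * pi * freqs) +
                         matrix(phases, n, carrier$n_components, byrow = TRUE)) %*%
                     rep(1, carrier$n_components))
    if (ramp_ms > 0) {
      nr <- min(round(ramp_ms / 1000 * fs), floor(n / 2))
      if (nr >= 2) {
        ramp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 1) / (nr - 1)))
        x[seq_len(nr)] <- x[seq_len(nr)] * ramp
        x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(ramp)
      }
    }
    x <- x / max(abs(x)) * carrier$gain
    structure(list(samples = x, duration_ms = duration_ms, carrier = carrier,
                   component_phases = phases),
              class = "narrowband_sound")
  })
}

#' Fraction of spectral energy inside a band
#'
#' Zero-padded periodogram estimate of the fraction of total power between
#' `lo` and `hi` Hz. Used to assert spectral containment of synthesized
#' narrowband sounds. Note that for very short gates the time-bandwidth
#' product limits attainable containment regardless of synthesis (a 10 ms
#' gate smears each component by roughly +/-100 Hz).
#'
#' @param samples Numeric waveform.
#' @param sample_rate Sampling rate in Hz.
#' @param lo,hi Band edges in Hz.
#' @return A number in (0, 1].
#' @export
spectral_containment <- function(samples, sample_rate, lo, hi) {
  if (inherits(samples, "narrowband_sound")) {
    snd <- samples
    samples <- snd$samples
    sample_rate <- snd$carrier$sample_rate
    if (missing(lo)) lo <- snd$carrier$center_freq - snd$carrier$bandwidth / 2
    if (missing(hi)) hi <- snd$carrier$center_freq + snd$carrier$bandwidth / 2
  }
  n <- length(samples)
  nfft <- 2^ceiling(log2(max(4 * n, 1024)))
  p <- Mod(fft(c(samples, numeric(nfft - n)))[seq_len(nfft %/% 2)])^2
  freqs <- (seq_len(nfft %/% 2) - 1) * sample_rate / nfft
  sum(p[freqs >= lo & freqs <= hi]) / sum(p)
}

#' Build a quintet stimulus
#'
#' A quintet is five 10 ms narrowband sounds with 10 ms gaps (onsets at 0,
#' 20, 40, 60, 80 ms; a 50 Hz inner rate, total active span 90 ms). A
#' target quintet displaces the third sound by `shift_ms`; the shift must
#' stay below 10 ms so the shifted sound never overlaps its neighbours.
#' The shift direction defaults to a delay (third sound later), which is a
#' package convention; the direction is configurable.
#'
#' @param carrier A [carrier_spec()].
#' @param shift_ms Temporal shift of the third sound in ms, `0 <= shift < 10`;
#'   0 gives a standard (non-target) quintet.
#' @param direction `"delay"` (default) or `"advance"`.
#' @param seed Optional integer seed (five fresh sounds are synthesized).
#' @return An object of class `quintet` with `sound_onsets_ms`, `shift_ms`,
#'   `is_target`, `samples` and `carrier`.
#' @export
build_quintet <- function(carrier, shift_ms = 0,
                          direction = c("delay", "advance"), seed = NULL) {
  stopifnot(inherits(carrier, "carrier_spec"))
  direction <- match.arg(direction)
  if (shift_ms < 0 || shift_ms >= 10)
    stop("`shift_ms` must lie in [0, 10) so the shifted sound cannot ",
         "overlap its neighbours", call. = FALSE)
  onsets <- c(0, 20, 40, 60, 80)
  onsets[3] <- onsets[3] + if (direction == "delay") shift_ms else -shift_ms
  fs <- carrier$sample_rate
  seeds <- if (is.null(seed)) rep(list(NULL), 5) else as.list(spawn_seeds(seed, 5))
  sounds <- lapply(seeds, function(s) synth_narrowband(carrier, 10, seed = s))
  n_total <- round((max(onsets) + 10) / 1000 * fs)
  samples <- numeric(n_total)
  for (k in 1:5) {
    i0 <- round(onsets[k] / 1000 * fs)
    idx <- i0 + seq_along(sounds[[k]]$samples)
    samples[idx] <- samples[idx] + sounds[[k]]$samples
  }
  structure(list(sound_onsets_ms = onsets, shift_ms = shift_ms,
                 is_target = shift_ms > 0, samples = samples,
                 carrier = carrier),
            class = "quintet")
}

#' Render a full sequence waveform
#'
#' Places a freshly synthesized quintet at every onset of a
#' [sequence_timing()] object inside a silence-padded waveform of exactly
#' the declared total duration. The quintet at `target_index` (if any) is
#' a target with the timing's `shift_ms`; all others are standard.
#'
#' @param timing A [sequence_timing()].
#' @param carrier A [carrier_spec()].
#' @param seed Optional integer seed.
#' @return Numeric waveform of length `round(total_duration_s * sample_rate)`
#'   with attributes `sample_rate` and `timing`.
#' @export
render_sequence <- function(timing, carrier, seed = NULL) {
  stopifnot(inherits(timing, "sequence_timing"), inherits(carrier, "carrier_spec"))
  fs <- carrier$sample_rate
  n_total <- round(timing$total_duration_s * fs)
  wave <- numeric(n_total)
  onsets <- timing$quintet_onsets_s
  nq <- length(onsets)
  if (nq == 0L)
    return(structure(wave, sample_rate = fs, timing = timing))
  spans <- rep(0.090, nq)
  if (!is.na(timing$target_index))
    spans[timing$target_index] <- 0.090 + timing$shift_ms / 1000
  if (any(onsets + spans > timing$total_duration_s + 1e-9))
    stop("quintet placement exceeds the declared total duration", call. = FALSE)
  if (nq > 1L && any(diff(onsets) < spans[-nq] - 1e-9))
    stop("overlapping quintets in sequence layout", call. = FALSE)
  seeds <- if (is.null(seed)) rep(list(NULL), nq) else as.list(spawn_seeds(seed, nq))
  for (k in seq_len(nq)) {
    shift <- if (!is.na(timing$target_index) && k == timing$target_index)
      timing$shift_ms else 0
    q <- build_quintet(carrier, shift, seed = seeds[[k]])
    i0 <- round(onsets[k] * fs)
    idx <- i0 + seq_along(q$samples)
    wave[idx] <- wave[idx] + q$samples
  }
  if (max(abs(wave)) > 1 + 1e-12)
    stop("rendered sequence clips (|amplitude| > 1)", call. = FALSE)
  structure(wave, sample_rate = fs, timing = timing)
}
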