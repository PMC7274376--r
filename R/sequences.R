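#' Sequence timing object
#'
#' Ordered quintet onsets for one trial plus condition labels, target
#' assignment and shift size. Usually constructed by [periodic_timing()],
#' [aperiodic_timing()] or [cue_timing()].
#'
#' @param condition `"periodic"`, `"aperiodic"` or `"cue"`.
#' @param rate_hz Nominal presentation rate in Hz.
#' @param quintet_onsets_s Strictly increasing onsets in seconds.
#' @param total_duration_s Declared sequence duration in seconds.
#' @param target_index 1-based quintet index of the target, or `NA` for a
#'   catch trial.
#' @param shift_ms Temporal shift of the target's third sound in ms.
#' @return An object of class `sequence_timing`.
#' @export
sequence_timing <- function(condition, rate_hz, quintet_onsets_s,
                            total_duration_s, target_index = NA_integer_,
                            shift_ms = 0) {
  condition <- match.arg(condition, c("periodic", "aperiodic", "cue"))
  n <- length(quintet_onsets_s)
  if (n > 1L && any(diff(quintet_onsets_s) <= 0))
    stop("quintet onsets must be strictly increasing", call. = FALSE)
  if (n > 0L && max(quintet_onsets_s) + 0.090 > total_duration_s + 1e-9)
    stop("last quintet span exceeds total duration", call. = FALSE)
  if (!is.na(target_index)) {
    if (target_index < 1L || target_index > n)
      stop("`target_index` out of range", call. = FALSE)
    if (shift_ms <= 0)
      stop("a target needs `shift_ms` > 0", call. = FALSE)
  }
  structure(list(condition = condition, rate_hz = rate_hz,
                 quintet_onsets_s = quintet_onsets_s,
                 total_duration_s = total_duration_s,
                 target_index = as.integer(target_index),
                 shift_ms = shift_ms),
            class = "sequence_timing")
}

#' @export
print.sequence_timing <- function(x, ...) {
  cat(sprintf("<sequence_timing> %s, %g Hz nominal, %d quintets in %g s, %s\n",
              x$condition, x$rate_hz, length(x$quintet_onsets_s),
              x$total_duration_s,
              if (is.na(x$target_index)) "catch"
              else sprintf("target at quintet %d (shift %g ms)",
                           x$target_index, x$shift_ms)))
  invisible(x)
}

#' Periodic (isochronous) sequence timing
#'
#' Quintet k (1-based) starts at `(k-1)/rate`; the sequence holds exactly
#' `rate_hz * total_duration_s` quintets (1 Hz for 12 s gives 12 quintets
#' with a 1 s onset-to-onset interval).
#'
#' @inheritParams sequence_timing
#' @param rate_hz Presentation rate, one of the study's 1, 2, 4, 8 Hz or
#'   any rate for which `rate_hz * total_duration_s` is whole.
#' @param total_duration_s Sequence duration in seconds (12 in the rate
#'   experiments, 6 in the threshold experiment).
#' @return A `sequence_timing`.
#' @export
periodic_timing <- function(rate_hz, total_duration_s, target_index = NA,
                            shift_ms = 0) {
  n <- rate_hz * total_duration_s
  if (abs(n - round(n)) > 1e-9)
    stop("`rate_hz * total_duration_s` must be a whole number of quintets",
         call. = FALSE)
  n <- as.integer(round(n))
  sequence_timing("periodic", rate_hz, (seq_len(n) - 1) / rate_hz,
                  total_duration_s, target_index, shift_ms)
}

#' Target quintet index for the two rate-experiment variants
#'
#' Variant `"1a"` keeps the ordinal position constant across rates (label
#' 9 means the 9th quintet at every rate, so faster rates place the target
#' earlier in time). Variant `"1b"` keeps the time constant: the index is
#' `position_label * rate`, so label 9 at 2 Hz is the 18th quintet,
#' landing at the same nominal time as the 9th quintet at 1 Hz.
#'
#' @param variant `"1a"` or `"1b"`.
#' @param rate_hz Presentation rate in Hz.
#' @param position_label Position label, one of 9, 10, 11 in the study.
#' @param n_quintets Quintet count of the sequence, used for range
#'   checking (optional).
#' @return Integer quintet index (1-based).
#' @export
assign_target <- function(variant, rate_hz, position_label,
                          n_quintets = NULL) {
  variant <- match.arg(as.character(variant), c("1a", "1b"))
  idx <- switch(variant,
                "1a" = position_label,
                "1b" = position_label * rate_hz)
  if (abs(idx - round(idx)) > 1e-9)
    stop("target index is not a whole number", call. = FALSE)
  idx <- as.integer(round(idx))
  if (!is.null(n_quintets) && idx > n_quintets)
    stop("target index ", idx, " exceeds quintet count ", n_quintets,
         call. = FALSE)
  idx
}

# Uniform mixture means (s) for the two aperiodic nominal rates; the short
# and long interval distributions bracket the periodic onset interval.
aperiodic_interval_means <- function(nominal_rate_hz) {
  switch(as.character(nominal_rate_hz),
         "1" = c(0.250, 1.500),
         "2" = c(0.100, 0.733),
         stop("aperiodic sequences exist only at nominal 1 or 2 Hz; faster ",
              "rates leave no room between quintets", call. = FALSE))
}

#' Aperiodic sequence timing
#'
#' Same quintet count and total duration as the periodic counterpart, but
#' with irregular onsets. Onset-to-onset intervals are drawn independently
#' with equal probability from two uniform distributions (half-width half
#' their mean) whose means bracket the periodic interval: 250 ms and
#' 1500 ms for nominal 1 Hz, 100 ms and 733 ms for nominal 2 Hz. The
#' interval vector is then rescaled so the last onset lands exactly where
#' the periodic counterpart's does, making count and duration match
#' exactly. Draws whose rescaled intervals would overlap quintets
#' (onset gap < 90 ms) are rejected and redrawn (at most `max_redraws`).
#'
#' @inheritParams sequence_timing
#' @param nominal_rate_hz 1 or 2.
#' @param seed Optional integer seed.
#' @param max_redraws Rejection-sampling bound (default 1000).
#' @return A `sequence_timing`.
#' @export
aperiodic_timing <- function(nominal_rate_hz, total_duration_s,
                             target_index = NA, shift_ms = 0, seed = NULL,
                             max_redraws = 1000) {
  means <- aperiodic_interval_means(nominal_rate_hz)
  n <- nominal_rate_hz * total_duration_s
  if (abs(n - round(n)) > 1e-9)
    stop("`nominal_rate_hz * total_duration_s` must be whole", call. = FALSE)
  n <- as.integer(round(n))
  span_target <- (n - 1) / nominal_rate_hz   # last onset of the periodic twin
  min_gap <- 0.090 + shift_ms / 1000
  with_seed(seed, {
    for (attempt in seq_len(max_redraws)) {
      which_dist <- sample(1:2, n - 1, replace = TRUE)
      m <- means[which_dist]
      iv <- runif(n - 1, 0.5 * m, 1.5 * m)
      iv <- iv * span_target / sum(iv)
      if (all(iv >= min_gap)) {
        return(sequence_timing("aperiodic", nominal_rate_hz,
                               c(0, cumsum(iv)), total_duration_s,
                               target_index, shift_ms))
      }
    }
    stop("could not draw a non-overlapping aperiodic layout in ",
         max_redraws, " attempts", call. = FALSE)
  })
}

#' Temporal-cue sequence timing
#'
#' Two quintets: a cue at time 0 and a probe at `isi_ms`. If `shift_ms > 0`
#' the probe is the target; `shift_ms = 0` gives a valid catch trial. The
#' study used a 500 ms cue-probe interval, matching the 2 Hz sequences.
#'
#' @param isi_ms Cue-to-probe onset interval in ms (>= 90, the quintet span).
#' @param shift_ms Target shift in ms (0 for a catch trial).
#' @return A `sequence_timing` with nominal rate `1000/isi_ms`.
#' @export
cue_timing <- function(isi_ms = 500, shift_ms = 0) {
  if (isi_ms < 90)
    stop("`isi_ms` must be >= 90 ms (quintet span), got overlap", call. = FALSE)
  total <- (isi_ms + 90 + shift_ms) / 1000
  sequence_timing("cue", 1000 / isi_ms, c(0, isi_ms / 1000), total,
                  target_index = if (shift_ms > 0) 2L else NA_integer_,
                  shift_ms = shift_ms)
}

#' Timing for one trial-manifest row
#'
#' Convenience dispatcher turning one row of a [build_session()] plan into
#' a [sequence_timing()], drawing aperiodic layouts with the given seed.
#'
#' @param trial One-row data frame (or list) with fields
#'   `temporal_condition`, `rate_hz`, `total_duration_s`, `target_index`,
#'   `shift_ms`.
#' @param seed Optional integer seed for aperiodic draws.
#' @return A `sequence_timing`.
#' @export
trial_timing <- function(trial, seed = NULL) {
  ti <- trial$target_index
  if (is.null(ti) || is.na(ti)) ti <- NA
  switch(as.character(trial$temporal_condition),
         periodic = periodic_timing(trial$rate_hz, trial$total_duration_s,
                                    ti, trial$shift_ms),
         aperiodic = aperiodic_timing(trial$rate_hz, trial$total_duration_s,
                                      ti, trial$shift_ms, seed = seed),
         cue = cue_timing(500, if (isTRUE(trial$target_present))
           trial$shift_ms else 0),
         stop("unknown temporal_condition: ", trial$temporal_condition,
              call. = FALSE))
}
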