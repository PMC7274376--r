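#' Adaptive staircase configuration
#'
#' Transformed up-down (2-down-1-up) track over a fixed logarithmic
#' ladder of temporal-shift sizes, as used to hold detection near the
#' 70.7% point: 10 log-spaced levels between 7 ms (easiest) and 1.5 ms
#' (hardest), terminating after 200 trials or 15 reversals, whichever
#' comes first.
#'
#' @param level_max_ms Easiest (largest) shift in ms (default 7).
#' @param level_min_ms Hardest (smallest) shift in ms (default 1.5).
#' @param n_levels Number of log-spaced levels (default 10).
#' @param n_down Consecutive correct responses required to step harder
#'   (default 2).
#' @param max_trials Trial cap (default 200).
#' @param max_reversals Reversal cap (default 15).
#' @return An object of class `staircase_config`.
#' @export
staircase_config <- function(level_max_ms = 7, level_min_ms = 1.5,
                             n_levels = 10, n_down = 2, max_trials = 200,
                             max_reversals = 15) {
  if (!(level_max_ms > level_min_ms && level_min_ms > 0))
    stop("need level_max_ms > level_min_ms > 0", call. = FALSE)
  if (n_levels < 2) stop("`n_levels` must be >= 2", call. = FALSE)
  structure(list(level_max_ms = level_max_ms, level_min_ms = level_min_ms,
                 n_levels = as.integer(n_levels), n_down = as.integer(n_down),
                 max_trials = as.integer(max_trials),
                 max_reversals = as.integer(max_reversals)),
            class = "staircase_config")
}

#' Staircase level ladder
#'
#' Geometric ladder from the easiest to the hardest level; adjacent levels
#' share a constant ratio (`(1.5/7)^(1/9) ~ 0.8427` for the defaults).
#'
#' @param config A [staircase_config()].
#' @return Numeric vector of `n_levels` shift sizes in ms, descending.
#' @export
staircase_levels <- function(config = staircase_config()) {
  lv <- exp(seq(log(config$level_max_ms), log(config$level_min_ms),
                length.out = config$n_levels))
  # snap the defining endpoints to their exact values
  lv[1] <- config$level_max_ms
  lv[config$n_levels] <- config$level_min_ms
  lv
}

#' Initialize a staircase state
#'
#' The track starts at the easiest level. The state records the ladder
#' position, the run of consecutive correct responses, reversal levels,
#' the direction of the last executed step, trial count and termination.
#'
#' @param config A [staircase_config()].
#' @return An object of class `staircase_state`.
#' @export
staircase_init <- function(config = staircase_config()) {
  structure(list(config = config, levels = staircase_levels(config),
                 level_index = 1L, n_correct = 0L, last_direction = 0L,
                 reversal_levels = numeric(0), trial_count = 0L,
                 terminated = FALSE),
            class = "staircase_state")
}

#' Current level of a staircase
#' @param state A `staircase_state`.
#' @return Shift size in ms.
#' @export
staircase_level <- function(state) state$levels[state$level_index]

#' Advance a staircase by one response
#'
#' 2-down-1-up rule: after `n_down` consecutive correct responses the
#' track steps one level harder (smaller shift) and the run counter
#' resets; any incorrect response steps one level easier. A step whose
#' direction differs from the previous executed step records the current
#' (pre-step) level as a reversal. Steps are clamped at the ladder ends;
#' clamped steps neither move the track nor count as reversals. The track
#' terminates at `max_trials` trials or `max_reversals` reversals.
#'
#' @param state A `staircase_state` (not yet terminated).
#' @param correct Logical response for the trial presented at the current
#'   level.
#' @return The updated `staircase_state`, with a `reversal` attribute
#'   flagging whether this update recorded a reversal.
#' @export
staircase_update <- function(state, correct) {
  if (state$terminated)
    stop("staircase already terminated", call. = FALSE)
  stopifnot(is.logical(correct), length(correct) == 1L, !is.na(correct))
  state$trial_count <- state$trial_count + 1L
  step <- 0L
  if (correct) {
    state$n_correct <- state$n_correct + 1L
    if (state$n_correct >= state$config$n_down) {
      step <- 1L                      # harder: down the ladder
      state$n_correct <- 0L
    }
  } else {
    state$n_correct <- 0L
    step <- -1L                       # easier: up the ladder
  }
  reversal <- FALSE
  if (step != 0L) {
    new_index <- state$level_index + step
    clamped <- new_index < 1L || new_index > state$config$n_levels
    if (!clamped) {
      if (state$last_direction != 0L && step != state$last_direction) {
        reversal <- TRUE
        state$reversal_levels <- c(state$reversal_levels,
                                   state$levels[state$level_index])
      }
      state$last_direction <- step
      state$level_index <- new_index
    }
  }
  if (state$trial_count >= state$config$max_trials ||
      length(state$reversal_levels) >= state$config$max_reversals)
    state$terminated <- TRUE
  attr(state, "reversal") <- reversal
  state
}

#' Threshold estimate from a completed track
#'
#' Geometric mean of the reversal levels after discarding the first two
#' (warm-up) reversals. The 2-down-1-up rule targets the 70.7% correct
#' point of the observer's psychometric function, so this estimate
#' approximates the shift detected on 70.7% of trials.
#'
#' @param state A `staircase_state` with at least 4 recorded reversals.
#' @return Threshold shift in ms.
#' @export
staircase_threshold <- function(state) {
  rv <- state$reversal_levels
  if (length(rv) < 4)
    stop("need >= 4 reversals to estimate a threshold (got ",
         length(rv), ")", call. = FALSE)
  geomean(rv[-(1:2)])
}

#' Run a full adaptive track against an observer
#'
#' Presents levels to `observer` (a function `level_ms -> logical`)
#' until the track terminates, recording a trial-by-trial trace.
#'
#' @param observer Function of the presented shift (ms) returning `TRUE`
#'   for a correct detection.
#' @param config A [staircase_config()].
#' @param seed Optional integer seed (observers typically draw from the
#'   RNG).
#' @return List with `threshold` (ms; `NA` when fewer than 4 reversals
#'   occurred, e.g. for a deterministic observer pinned at one ladder
#'   end), `state`, and `trace` (data frame: `trial`, `level_ms`,
#'   `correct`, `reversal`).
#' @export
run_staircase <- function(observer, config = staircase_config(),
                          seed = NULL) {
  with_seed(seed, {
    state <- staircase_init(config)
    m <- config$max_trials
    level <- numeric(m); corr <- logical(m); rev_ <- logical(m)
    i <- 0L
    while (!state$terminated) {
      i <- i + 1L
      level[i] <- staircase_level(state)
      corr[i] <- isTRUE(observer(level[i]))
      state <- staircase_update(state, corr[i])
      rev_[i] <- attr(state, "reversal")
    }
    trace <- data.frame(trial = seq_len(i), level_ms = level[seq_len(i)],
                        correct = corr[seq_len(i)],
                        reversal = rev_[seq_len(i)])
    threshold <- tryCatch(staircase_threshold(state),
                          error = function(e) NA_real_)
    list(threshold = threshold, state = state, trace = trace)
  })
}
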