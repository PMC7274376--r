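#' Simulated SDT observer parameters
#'
#' An equal-variance Gaussian signal-detection observer whose sensitivity
#' depends on the design cell. Sensitivity follows a power-law
#' psychometric in the shift magnitude around the 6 ms reference,
#' `d'(shift) = d_ref (shift/6)^gamma`, plus additive offsets per rhythm,
#' carrier, temporal condition and target position, floored at 0. Yes/no
#' responses follow `P(yes | target) = (1-lapse) Phi(d'/2 - c) + lapse/2`
#' and `P(yes | no target) = (1-lapse) Phi(-d'/2 - c) + lapse/2`.
#' Correct yes responses get log-normal reaction times (relative to
#' target onset) with condition-dependent location offsets.
#'
#' Default offsets are the study's published unstandardized effect sizes
#' (d': 2/4/8 Hz vs 1 Hz = +0.0750/-0.4874/-1.0152; 200/3100 Hz vs
#' 1100 Hz = +0.0983/-0.8381; periodic/cue vs aperiodic =
#' +0.5903/+0.7154; logRT: periodic/cue vs aperiodic = -0.3317/-0.6647;
#' 200/3100 Hz vs 1100 Hz = -0.1078/+0.0631). Position offsets default to
#' 0 (unconstrained by the study). The default lapse is 0 so the
#' generator matches the statistical structure the analysis assumes.
#'
#' @param d_ref d' at the 6 ms reference shift in the reference cell
#'   (default 2).
#' @param gamma Psychometric exponent (default 1.3).
#' @param criterion Response criterion c (default 0.25).
#' @param lapse Lapse rate in `[0, 0.5)` (default 0).
#' @param rhythm_offsets,carrier_offsets,condition_offsets,position_offsets
#'   Named numeric vectors of additive d' offsets (reference levels 1 Hz,
#'   1100 Hz, aperiodic).
#' @param rt_mu Location of log reaction time (s) in the reference cell
#'   (default `log(0.75)`).
#' @param rt_sigma Scale of log reaction time (default 0.35).
#' @param rt_condition_offsets,rt_carrier_offsets Additive log-RT offsets.
#' @param subject_sd_dprime,subject_sd_criterion Between-subject normal
#'   SDs on `d_ref` and `criterion` (defaults 0.2), the generative twin
#'   of a subject random intercept.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(
    d_ref = 2.0, gamma = 1.3, criterion = 0.25, lapse = 0,
    rhythm_offsets = c("1" = 0, "2" = 0.0750, "4" = -0.4874, "8" = -1.0152),
    carrier_offsets = c("200" = 0.0983, "1100" = 0, "3100" = -0.8381),
    condition_offsets = c(aperiodic = 0, periodic = 0.5903, cue = 0.7154),
    position_offsets = c("9" = 0, "10" = 0, "11" = 0),
    rt_mu = log(0.75), rt_sigma = 0.35,
    rt_condition_offsets = c(aperiodic = 0, periodic = -0.3317,
                             cue = -0.6647),
    rt_carrier_offsets = c("200" = -0.1078, "1100" = 0, "3100" = 0.0631),
    subject_sd_dprime = 0.2, subject_sd_criterion = 0.2) {
  if (lapse < 0 || lapse >= 0.5)
    stop("`lapse` must lie in [0, 0.5)", call. = FALSE)
  if (rt_sigma <= 0) stop("`rt_sigma` must be > 0", call. = FALSE)
  structure(list(
    d_ref = d_ref, gamma = gamma, criterion = criterion, lapse = lapse,
    rhythm_offsets = rhythm_offsets, carrier_offsets = carrier_offsets,
    condition_offsets = condition_offsets,
    position_offsets = position_offsets,
    rt_mu = rt_mu, rt_sigma = rt_sigma,
    rt_condition_offsets = rt_condition_offsets,
    rt_carrier_offsets = rt_carrier_offsets,
    subject_sd_dprime = subject_sd_dprime,
    subject_sd_criterion = subject_sd_criterion),
    class = "observer_params")
}

lookup_offset <- function(offsets, key) {
  v <- offsets[as.character(key)]
  v[is.na(v)] <- 0
  unname(v)
}

# Vectorized cell d' (before flooring the observer never sees negative d').
cell_dprime <- function(params, shift_ms, rate_hz, carrier_hz,
                        temporal_condition, position_label = NA,
                        d_ref_jitter = 0) {
  base <- (params$d_ref + d_ref_jitter) * (shift_ms / 6)^params$gamma
  pmax(0, base +
         lookup_offset(params$rhythm_offsets, rate_hz) +
         lookup_offset(params$carrier_offsets, carrier_hz) +
         lookup_offset(params$condition_offsets, temporal_condition) +
         ifelse(is.na(position_label), 0,
                lookup_offset(params$position_offsets, position_label)))
}

#' d' of the observer for one trial
#'
#' @param params An [observer_params()].
#' @param trial One-row data frame or list with `shift_ms`, `rate_hz`,
#'   `carrier_hz`, `temporal_condition` and optionally `position_label`.
#' @return The cell's generating d' (floored at 0).
#' @export
dprime_for_trial <- function(params, trial) {
  cell_dprime(params, trial$shift_ms, trial$rate_hz, trial$carrier_hz,
              trial$temporal_condition,
              trial$position_label %||% NA)
}

#' Simulate the yes/no response (and RT) for one trial
#'
#' @inheritParams dprime_for_trial
#' @param trial As in [dprime_for_trial()], plus `target_present`,
#'   `target_index` and `total_duration_s`.
#' @param seed Optional integer seed.
#' @return The trial as a one-row data frame with `response`
#'   (`"yes"`/`"no"`), `correct` and `rt_s` appended.
#' @export
simulate_response <- function(params, trial, seed = NULL) {
  trial <- as.data.frame(trial)
  with_seed(seed, simulate_rows(params, trial, d_jit = 0, c_jit = 0))
}

# Vectorized core: one cohort-row per plan-row, given per-row subject
# jitters. Assumes RNG state is managed by the caller.
simulate_rows <- function(params, rows, d_jit, c_jit) {
  n <- nrow(rows)
  # the noise-distribution placement on catch trials uses the cell's d',
  # i.e. the shift presented on target trials of the same cell
  cell_shift <- rows$cell_shift %||% ifelse(rows$shift_ms > 0, rows$shift_ms, 6)
  d <- cell_dprime(params,
                   ifelse(rows$target_present, rows$shift_ms, cell_shift),
                   rows$rate_hz, rows$carrier_hz, rows$temporal_condition,
                   rows$position_label %||% NA, d_ref_jitter = d_jit)
  cc <- params$criterion + c_jit
  p_yes <- ifelse(rows$target_present,
                  (1 - params$lapse) * pnorm(d / 2 - cc) + params$lapse / 2,
                  (1 - params$lapse) * pnorm(-d / 2 - cc) + params$lapse / 2)
  yes <- runif(n) < p_yes
  correct <- yes == rows$target_present
  # target onset time: nominal (index-1)/rate for sequences, the probe
  # onset for cue trials
  t_target <- ifelse(rows$temporal_condition == "cue", 0.5,
                     (ifelse(is.na(rows$target_index), 1,
                             rows$target_index) - 1) / rows$rate_hz)
  window <- rows$total_duration_s - t_target + 1
  mu <- params$rt_mu +
    lookup_offset(params$rt_condition_offsets, rows$temporal_condition) +
    lookup_offset(params$rt_carrier_offsets, rows$carrier_hz)
  rt <- rep(NA_real_, n)
  hit <- yes & rows$target_present
  fa <- yes & !rows$target_present
  rt[hit] <- pmin(exp(mu[hit] + params$rt_sigma * rnorm(sum(hit))),
                  window[hit])
  rt[fa] <- runif(sum(fa), 0, rows$total_duration_s[fa])
  rows$response <- ifelse(yes, "yes", "no")
  rows$correct <- correct
  rows$rt_s <- rt
  rows
}

#' Simulate a full cohort trial log
#'
#' Runs the observer over every trial of one or more [build_session()]
#' plans. Per-subject sensitivity and criterion perturbations are drawn
#' from the between-subject normals in `params`. When the plan's target
#' `shift_ms` is `NA` (experiment-2 sessions), a 2-down-1-up staircase is
#' run against the subject's own psychometric before each block and the
#' resulting threshold (clamped to the ladder range) is used as the
#' block's target shift; the staircase trials use the block's aperiodic
#' reference cell.
#'
#' @param params An [observer_params()].
#' @param plan A `session_plan` from [build_session()].
#' @param seed Integer master seed.
#' @param staircase `"block"` (default; one track per subject x block
#'   when shifts are `NA`) or `"subject"` (one track per subject).
#' @param include_staircase_trace If `TRUE`, staircase trials are
#'   appended to the returned table with `phase = "staircase"`.
#' @return A trial-log data frame (see [trial_log_columns()]); one row
#'   per main trial (plus staircase rows if requested).
#' @export
simulate_dataset <- function(params, plan, seed = NULL,
                             staircase = c("block", "subject"),
                             include_staircase_trace = FALSE) {
  staircase <- match.arg(staircase)
  subjects <- unique(plan$subject)
  seeds <- if (is.null(seed)) rep(list(NULL), length(subjects))
           else as.list(spawn_seeds(seed, length(subjects)))
  out <- vector("list", length(subjects))
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    rows <- plan[plan$subject == s, , drop = FALSE]
    out[[si]] <- with_seed(seeds[[si]], {
      d_jit <- rnorm(1, 0, params$subject_sd_dprime)
      c_jit <- rnorm(1, 0, params$subject_sd_criterion)
      stair_rows <- NULL
      if (anyNA(rows$shift_ms[rows$target_present])) {
        ladder <- staircase_levels(staircase_config())
        blocks <- if (staircase == "block") unique(rows$block) else 1L
        for (b in blocks) {
          sel <- if (staircase == "block")
            rows$target_present & rows$block == b else rows$target_present
          ref <- rows[which(sel)[1], ]
          obs <- function(level_ms) {
            d <- cell_dprime(params, level_ms, ref$rate_hz, ref$carrier_hz,
                             "aperiodic", NA, d_ref_jitter = d_jit)
            runif(1) < (1 - params$lapse) *
              pnorm(d / 2 - (params$criterion + c_jit)) + params$lapse / 2
          }
          tr <- run_staircase(obs)
          thr <- tr$threshold
          if (is.na(thr)) thr <- geomean(range(ladder))
          thr <- min(max(thr, min(ladder)), max(ladder))
          rows$shift_ms[sel & is.na(rows$shift_ms)] <- thr
          if (include_staircase_trace) {
            st <- data.frame(
              subject = s, block = if (staircase == "block") b else NA,
              trial = tr$trace$trial, phase = "staircase",
              variant = ref$variant, temporal_condition = "aperiodic",
              rate_hz = ref$rate_hz, carrier_hz = ref$carrier_hz,
              total_duration_s = ref$total_duration_s,
              position_label = NA_real_, target_index = NA_integer_,
              target_present = TRUE, shift_ms = tr$trace$level_ms,
              response = ifelse(tr$trace$correct, "yes", "no"),
              correct = tr$trace$correct, rt_s = NA_real_)
            stair_rows <- rbind(stair_rows, st)
          }
        }
      }
      rows$cell_shift <- stats::ave(
        ifelse(rows$target_present, rows$shift_ms, 0),
        rows$block, rows$temporal_condition, FUN = max)
      rows$cell_shift[rows$cell_shift <= 0] <- 6
      main <- simulate_rows(params, rows, d_jit = d_jit, c_jit = c_jit)
      main$cell_shift <- NULL
      if (is.null(stair_rows)) main else rbind(main, stair_rows)
    })
  }
  res <- do.call(rbind, out)
  res$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  rownames(res) <- NULL
  res
}
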