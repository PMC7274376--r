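#' Build counterbalanced session plans
#'
#' Lays out every trial of a session for each subject, following the
#' study's design table:
#'
#' * `"1a"`, `"1b"`: periodic 12 s sequences, rates 1/2/4/8 Hz, carriers
#'   200/1100/3100 Hz, 6 ms shift; 40 blocks of 12 trials grouped by
#'   rhythm (10 cycles of the four rates), 480 trials. Within each block
#'   the 9 target trials cover each (position x carrier) cell once and the
#'   3 catch trials cover each carrier once. Variant 1a fixes the target's
#'   ordinal position (quintets 9-11); 1b fixes its time (label x rate).
#' * `"2"`: 6 s sequences at 2 Hz, carrier 1100 Hz; 6 blocks of 72 trials,
#'   each block holding three 24-trial groups (periodic, aperiodic, cue);
#'   432 trials. Target shift is left `NA` to be set per block by an
#'   adaptive staircase (or pass `shift_ms` to fix it).
#' * `"pilot"`: aperiodic 12 s sequences at nominal 1 and 2 Hz, carrier
#'   1100 Hz, 6 ms shift; 5 blocks of 16 trials (rate constant within a
#'   block), 80 trials.
#'
#' Every variant has exactly 75% target trials. Block (or within-block
#' group) order is counterbalanced across subjects by Latin-square
#' rotation; trial order within blocks is randomized reproducibly from
#' `seed`.
#'
#' @param variant `"1a"`, `"1b"`, `"2"` or `"pilot"`.
#' @param n_subjects Number of subjects to plan (default 1).
#' @param seed Integer master seed.
#' @param shift_ms Target shift in ms; defaults to 6 for variants
#'   1a/1b/pilot and `NA` (staircase-determined) for variant 2.
#' @return A data frame of class `session_plan`, one row per trial, with
#'   columns `subject`, `block`, `trial`, `phase`, `variant`,
#'   `temporal_condition`, `rate_hz`, `carrier_hz`, `total_duration_s`,
#'   `position_label`, `target_index`, `target_present`, `shift_ms`.
#' @export
build_session <- function(variant = c("1a", "1b", "2", "pilot"),
                          n_subjects = 1, seed = NULL, shift_ms = NULL) {
  variant <- match.arg(as.character(variant), c("1a", "1b", "2", "pilot"))
  if (is.null(shift_ms))
    shift_ms <- if (variant == "2") NA_real_ else 6
  seeds <- if (is.null(seed)) rep(list(NULL), n_subjects)
           else as.list(spawn_seeds(seed, n_subjects))
  plans <- lapply(seq_len(n_subjects), function(s) {
    p <- switch(variant,
                "1a" = , "1b" = session_exp1(variant, s, shift_ms, seeds[[s]]),
                "2"  = session_exp2(s, shift_ms, seeds[[s]]),
                "pilot" = session_pilot(s, shift_ms, seeds[[s]]))
    p$trial <- seq_len(nrow(p))
    cbind(subject = s, p[c("block", "trial")],
          phase = "main", variant = variant,
          p[setdiff(names(p), c("block", "trial"))])
  })
  out <- do.call(rbind, plans)
  rownames(out) <- NULL
  structure(out, variant = variant, seed = seed,
            class = c("session_plan", "data.frame"))
}

# One 12-trial rate block: 9 targets (3 positions x 3 carriers) + 3 catch
# (one per carrier), shuffled.
exp1_block <- function(variant, rate, carriers, positions, shift_ms) {
  tg <- expand.grid(position_label = positions, carrier_hz = carriers)
  tg$target_index <- vapply(tg$position_label, function(p)
    assign_target(variant, rate, p, n_quintets = rate * 12), integer(1))
  tg$target_present <- TRUE
  tg$shift_ms <- shift_ms
  ct <- data.frame(position_label = NA_real_, carrier_hz = carriers,
                   target_index = NA_integer_, target_present = FALSE,
                   shift_ms = 0)
  blk <- rbind(tg, ct)
  blk[sample.int(nrow(blk)), , drop = FALSE]
}

session_exp1 <- function(variant, subject, shift_ms, seed) {
  rates <- c(1, 2, 4, 8)
  carriers <- c(200, 1100, 3100)
  positions <- c(9, 10, 11)
  with_seed(seed, {
    rate_order <- rates[((seq_along(rates) - 1 + (subject - 1)) %% 4) + 1]
    blocks <- vector("list", 40)
    for (cycle in 1:10) {
      for (j in 1:4) {
        b <- (cycle - 1) * 4 + j
        blk <- exp1_block(variant, rate_order[j], carriers, positions,
                          shift_ms)
        blk <- cbind(block = b, temporal_condition = "periodic",
                     rate_hz = rate_order[j], blk)
        blocks[[b]] <- blk
      }
    }
    out <- do.call(rbind, blocks)
    out$total_duration_s <- 12
    out[c("block", "temporal_condition", "rate_hz", "carrier_hz",
          "total_duration_s", "position_label", "target_index",
          "target_present", "shift_ms")]
  })
}

# One 24-trial condition group: 18 targets + 6 catch. Periodic/aperiodic
# targets cover the three late positions (quintets 9-11 of 12) six times
# each; cue targets sit on the probe quintet.
exp2_group <- function(condition, shift_ms) {
  if (condition == "cue") {
    tg <- data.frame(position_label = NA_real_,
                     target_index = 2L, target_present = TRUE,
                     shift_ms = shift_ms)[rep(1, 18), ]
  } else {
    tg <- data.frame(position_label = rep(c(9, 10, 11), each = 6))
    tg$target_index <- as.integer(tg$position_label)
    tg$target_present <- TRUE
    tg$shift_ms <- shift_ms
  }
  ct <- data.frame(position_label = NA_real_, target_index = NA_integer_,
                   target_present = FALSE, shift_ms = 0)[rep(1, 6), ]
  grp <- rbind(tg, ct)
  grp <- grp[sample.int(nrow(grp)), , drop = FALSE]
  grp$temporal_condition <- condition
  grp$rate_hz <- 2
  grp$carrier_hz <- 1100
  grp$total_duration_s <- ifelse(condition == "cue", 0.59, 6)
  grp
}

session_exp2 <- function(subject, shift_ms, seed) {
  conds <- c("periodic", "aperiodic", "cue")
  with_seed(seed, {
    blocks <- vector("list", 6)
    for (b in 1:6) {
      ord <- conds[((seq_along(conds) - 1 + (subject - 1) + (b - 1)) %% 3) + 1]
      grp <- do.call(rbind, lapply(ord, exp2_group, shift_ms = shift_ms))
      blocks[[b]] <- cbind(block = b, grp)
    }
    out <- do.call(rbind, blocks)
    out[c("block", "temporal_condition", "rate_hz", "carrier_hz",
          "total_duration_s", "position_label", "target_index",
          "target_present", "shift_ms")]
  })
}

# Pilot: 16-trial aperiodic blocks, 12 targets (4 per position) + 4 catch;
# target time fixed across rates (1b rule).
session_pilot <- function(subject, shift_ms, seed) {
  rates <- c(1, 2)
  with_seed(seed, {
    blocks <- vector("list", 5)
    for (b in 1:5) {
      rate <- rates[((b - 1 + (subject - 1)) %% 2) + 1]
      tg <- data.frame(position_label = rep(c(9, 10, 11), each = 4))
      tg$target_index <- vapply(tg$position_label, function(p)
        assign_target("1b", rate, p, n_quintets = rate * 12), integer(1))
      tg$target_present <- TRUE
      tg$shift_ms <- shift_ms
      ct <- data.frame(position_label = NA_real_, target_index = NA_integer_,
                       target_present = FALSE, shift_ms = 0)[rep(1, 4), ]
      blk <- rbind(tg, ct)
      blk <- blk[sample.int(nrow(blk)), , drop = FALSE]
      blk <- cbind(block = b, temporal_condition = "aperiodic",
                   rate_hz = rate, carrier_hz = 1100,
                   total_duration_s = 12, blk)
      blocks[[b]] <- blk
    }
    out <- do.call(rbind, blocks)
    out[c("block", "temporal_condition", "rate_hz", "carrier_hz",
          "total_duration_s", "position_label", "target_index",
          "target_present", "shift_ms")]
  })
}
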