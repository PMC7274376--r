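# run tests under a fixed seed regardless of how the suite is loaded
with_seed <- tempshift:::with_seed

# Stochastic observer with a log-Gaussian psychometric: p(correct | shift)
# crosses 70.7% at `p707_ms`. Used for staircase convergence checks.
make_psychometric_observer <- function(p707_ms, slope = 0.5) {
  z707 <- qnorm(sqrt(0.5))
  function(level_ms) {
    p <- pnorm((log(level_ms) - log(p707_ms)) / slope + z707)
    runif(1) < p
  }
}

# Minimal trial table with exact hit/false-alarm counts per cell, for
# closed-form SDT oracles. `cells` is a data.frame of cell labels; counts
# are vectors aligned with its rows.
make_count_table <- function(cells, n_target, n_hit, n_catch, n_fa,
                             subject = 1L) {
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, , drop = FALSE]
    n <- n_target[i] + n_catch[i]
    data.frame(
      subject = subject, block = 1L, phase = "main",
      cell[rep(1, n), , drop = FALSE],
      target_present = rep(c(TRUE, FALSE), c(n_target[i], n_catch[i])),
      response = rep(c("yes", "no", "yes", "no"),
                     c(n_hit[i], n_target[i] - n_hit[i], n_fa[i],
                       n_catch[i] - n_fa[i])),
      row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$correct <- (out$response == "yes") == out$target_present
  out
}

# Small observer cohort on the threshold-experiment design, trimmed to
# `n_blocks` blocks for test speed.
quick_cohort <- function(n_subjects, seed, shift_ms = 5, n_blocks = 6,
                         params = observer_params()) {
  plan <- build_session("2", n_subjects, seed = seed, shift_ms = shift_ms)
  plan <- plan[plan$block <= n_blocks, , drop = FALSE]
  simulate_dataset(params, plan, seed = seed + 1L)
}

# The shift (ms) at which the default mean observer's aperiodic
# threshold-experiment cell sits exactly at the 2-down-1-up fixed point
# (70.7% yes on target trials).
default_threshold_shift <- function(params = observer_params()) {
  d_target <- 2 * (qnorm(sqrt(0.5)) + params$criterion)
  offs <- unname(params$rhythm_offsets["2"] + params$carrier_offsets["1100"] +
                   params$condition_offsets["aperiodic"])
  6 * ((d_target - offs) / params$d_ref)^(1 / params$gamma)
}
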