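test_that("periodic_timing produces isochronous onsets", {
  t1 <- periodic_timing(1, 12)
  expect_length(t1$quintet_onsets_s, 12)
  expect_equal(t1$quintet_onsets_s, 0:11)

  t2 <- periodic_timing(2, 6)
  expect_length(t2$quintet_onsets_s, 12)
  expect_equal(unique(diff(t2$quintet_onsets_s)), 0.5)

  expect_length(periodic_timing(8, 12)$quintet_onsets_s, 96)
  expect_error(periodic_timing(1.5, 5), "whole number")
})

test_that("assign_target follows the two variant rules", {
  # 1a: constant ordinal position; 1b: constant time (index = label * rate)
  expect_equal(assign_target("1a", 2, 9), 9L)
  expect_equal(assign_target("1b", 2, 9), 18L)
  expect_equal(assign_target("1b", 1, 9), 9L)
  expect_equal(assign_target("1b", 8, 11, n_quintets = 96), 88L)
  expect_error(assign_target("1b", 8, 13, n_quintets = 96), "exceeds")
})

test_that("aperiodic sequences match their periodic counterpart exactly", {
  for (seed in 1:25) {
    a1 <- aperiodic_timing(1, 12, seed = seed)
    p1 <- periodic_timing(1, 12)
    expect_length(a1$quintet_onsets_s, length(p1$quintet_onsets_s))
    expect_equal(max(a1$quintet_onsets_s), max(p1$quintet_onsets_s))
    expect_equal(a1$total_duration_s, 12)
    expect_gte(min(diff(a1$quintet_onsets_s)), 0.09)

    a2 <- aperiodic_timing(2, 6, seed = seed)
    expect_length(a2$quintet_onsets_s, 12)
    expect_equal(max(a2$quintet_onsets_s), 5.5)
    expect_gte(min(diff(a2$quintet_onsets_s)), 0.09)
  }
  expect_error(aperiodic_timing(4, 12, seed = 1), "1 or 2")
})

test_that("aperiodic intervals come from the two stated distributions", {
  # pooled over seeds the interval set is a half-width-m/2 uniform
  # mixture around means (0.25, 1.5) s at 1 Hz, rescaled to fit; the
  # achieved average interval is exactly the periodic one
  ivs <- unlist(lapply(1:200, function(s)
    diff(aperiodic_timing(1, 12, seed = s)$quintet_onsets_s)))
  expect_equal(mean(ivs), 1, tolerance = 0.02)
  # bimodal: sparse near the periodic interval itself (the exact-duration
  # rescaling smears the mixture components slightly)
  expect_lt(mean(ivs > 0.6 & ivs < 0.85), 0.05)
  short <- ivs[ivs < 0.6]; long <- ivs[ivs >= 0.6]
  expect_equal(length(short) / length(ivs), 0.5, tolerance = 0.05)
  expect_equal(mean(long) / mean(short), 1.5 / 0.25, tolerance = 0.15)
})

test_that("aperiodic draws are reproducible and bounded", {
  expect_identical(aperiodic_timing(2, 6, seed = 9)$quintet_onsets_s,
                   aperiodic_timing(2, 6, seed = 9)$quintet_onsets_s)
  expect_error(aperiodic_timing(2, 6, seed = 1, max_redraws = 0),
               "attempts")
})

test_that("cue_timing builds cue-probe pairs", {
  ct <- cue_timing(500, 6)
  expect_equal(ct$quintet_onsets_s, c(0, 0.5))
  expect_equal(ct$target_index, 2L)
  expect_equal(ct$condition, "cue")

  catch <- cue_timing(500, 0)
  expect_true(is.na(catch$target_index))
  expect_error(cue_timing(80, 6), "90")
})

test_that("build_session produces the study trial counts and prevalence", {
  counts <- c("1a" = 480L, "1b" = 480L, "2" = 432L, "pilot" = 80L)
  for (v in names(counts)) {
    plan <- build_session(v, n_subjects = 1, seed = 11)
    expect_identical(nrow(plan), counts[[v]])
    expect_equal(mean(plan$target_present), 0.75)
    expect_false(any(plan$target_present & !is.na(plan$shift_ms) &
                       plan$shift_ms <= 0))
    expect_true(all(is.na(plan$target_index[!plan$target_present])))
  }
})

test_that("exp-1 blocks are counterbalanced over position and carrier", {
  plan <- build_session("1a", n_subjects = 1, seed = 3)
  tg <- plan[plan$target_present, ]
  cell_counts <- table(tg$position_label, tg$carrier_hz)
  expect_true(all(cell_counts == cell_counts[1, 1]))
  # catch carriers balanced too
  expect_true(all(table(plan$carrier_hz[!plan$target_present]) == 40))
  # blocks grouped by rhythm: one rate per block, each rate 10 times
  rate_by_block <- unique(plan[c("block", "rate_hz")])
  expect_equal(nrow(rate_by_block), 40)
  expect_true(all(table(rate_by_block$rate_hz) == 10))
})

test_that("variant 1b uses constant-time target indices", {
  plan <- build_session("1b", n_subjects = 1, seed = 3)
  tg <- plan[plan$target_present, ]
  expect_true(all(tg$target_index == tg$position_label * tg$rate_hz))
  plan_a <- build_session("1a", n_subjects = 1, seed = 3)
  tga <- plan_a[plan_a$target_present, ]
  expect_true(all(tga$target_index == tga$position_label))
})

test_that("exp-2 sessions group conditions within blocks, counterbalanced", {
  plan <- build_session("2", n_subjects = 3, seed = 5)
  for (s in 1:3) {
    ps <- plan[plan$subject == s, ]
    expect_equal(nrow(ps), 432)
    expect_true(all(table(ps$temporal_condition) == 144))
    # 24 trials per condition per block
    expect_true(all(table(ps$block, ps$temporal_condition) == 24))
  }
  # block order differs across subjects (Latin-square rotation)
  first_cond <- sapply(1:3, function(s) {
    ps <- plan[plan$subject == s & plan$block == 1, ]
    ps$temporal_condition[1]
  })
  expect_equal(length(unique(first_cond)), 3)
  # target shift deferred to the staircase
  expect_true(all(is.na(plan$shift_ms[plan$target_present])))
  # but fixable
  pf <- build_session("2", 1, seed = 5, shift_ms = 5)
  expect_true(all(pf$shift_ms[pf$target_present] == 5))
})

test_that("session plans are reproducible from the master seed", {
  expect_identical(build_session("2", 2, seed = 42),
                   build_session("2", 2, seed = 42))
  # different seeds shuffle trial order within condition groups
  p1 <- build_session("2", 2, seed = 42)
  p2 <- build_session("2", 2, seed = 43)
  expect_false(identical(p1$target_present, p2$target_present))
})
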