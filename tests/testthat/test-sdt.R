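test_that("rates counts hits and false alarms per cell", {
  cells <- data.frame(temporal_condition = c("aperiodic", "periodic", "cue"))
  tab <- make_count_table(cells, n_target = c(40, 40, 40),
                          n_hit = c(30, 35, 36), n_catch = c(20, 20, 20),
                          n_fa = c(5, 2, 1))
  r <- rates(tab, "temporal_condition")
  expect_equal(nrow(r), 3)
  expect_equal(r$hit[r$temporal_condition == "aperiodic"], 0.75)
  expect_equal(r$fa[r$temporal_condition == "cue"], 0.05)
  expect_equal(sum(r$n_target), 120)

  # pooled call, no grouping
  rp <- rates(tab)
  expect_equal(rp$hit, 101 / 120)

  # all-catch cell flagged
  tab2 <- tab[!(tab$temporal_condition == "cue" & tab$target_present), ]
  expect_warning(r2 <- rates(tab2, "temporal_condition"), "lack")
  expect_true(is.na(r2$hit[r2$temporal_condition == "cue"]))

  expect_error(rates(tab, "nonexistent"), "missing columns")
})

test_that("dprime_classic matches the inverse-normal closed form", {
  expect_equal(dprime_classic(0.5, 0.5), 0)
  expect_equal(dprime_classic(0.9, 0.1), 2.563103, tolerance = 1e-6)
  expect_equal(dprime_classic(0.75, 0.25), 2 * qnorm(0.75))
  # log-linear shrinkage keeps perfect rates finite:
  # (24 + .5)/25 = .98, (0 + .5)/25 = .02
  d <- dprime_classic(1, 0, "loglinear", n_target = 24, n_catch = 24)
  expect_equal(d, qnorm(0.98) - qnorm(0.02))
  expect_true(is.finite(d))
  expect_error(dprime_classic(1, 0.1), "loglinear")
  expect_error(dprime_classic(1.2, 0.1), "\\[0, 1\\]")
})

test_that("sdt_design builds the -1 criterion coding and dummy scheme", {
  cells <- data.frame(temporal_condition = c("aperiodic", "periodic", "cue"))
  tab <- make_count_table(cells, c(40, 40, 40), c(30, 35, 36),
                          c(20, 20, 20), c(5, 2, 1))
  des <- sdt_design(tab, "temporal_condition")
  expect_true(all(des$X[, "Criterion"] == -1))
  expect_setequal(colnames(des$X),
                  c("Criterion", "Target", "temporal_conditionperiodic",
                    "temporal_conditioncue",
                    "Target:temporal_conditionperiodic",
                    "Target:temporal_conditioncue"))
  expect_true(all(des$X[, "Target"] %in% 0:1))
})

test_that("saturated probit fit reproduces the classical d' closed form", {
  tab <- make_count_table(data.frame(cell = "a"), 40, 30, 40, 10)
  fit <- fit_probit(sdt_design(tab))
  expect_equal(unname(coef(fit)["Target"]),
               qnorm(0.75) - qnorm(0.25), tolerance = 1e-9)
  expect_equal(unname(coef(fit)["Target"]), 1.34898, tolerance = 1e-5)
  # Criterion column is coded -1, so beta0 = -qnorm(fa)
  expect_equal(unname(coef(fit)["Criterion"]), -qnorm(0.25),
               tolerance = 1e-9)
})

test_that("fit_probit agrees with stats::glm on random designs", {
  for (s in 1:10) {
    tab <- with_seed(s, {
      cells <- data.frame(cell = letters[1:3])
      nt <- sample(20:50, 3); nc <- sample(20:50, 3)
      make_count_table(cells, nt,
                       vapply(nt, function(n) sample(seq(2, n - 2), 1), 1L),
                       nc,
                       vapply(nc, function(n) sample(seq(2, n - 2), 1), 1L))
    })
    des <- sdt_design(tab, "cell")
    ours <- fit_probit(des)
    ref <- suppressWarnings(
      stats::glm.fit(des$X, des$y, family = stats::binomial("probit")))
    expect_equal(unname(coef(ours)), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(ours$logLik,
                 probit_ll <- sum(stats::dbinom(des$y, 1,
                                                ref$fitted.values,
                                                log = TRUE)),
                 tolerance = 1e-8)
  }
})

test_that("fit_probit flags degenerate designs", {
  tab <- make_count_table(data.frame(cell = "a"), 40, 30, 40, 10)
  des <- sdt_design(tab)
  des$X <- cbind(des$X, dup = des$X[, "Target"])
  expect_error(fit_probit(des), "rank deficient")

  # perfectly separated single cell (all hits, no false alarms)
  sep <- make_count_table(data.frame(cell = "a"), 40, 40, 40, 0)
  expect_error(fit_probit(sdt_design(sep)), "separat")
})

test_that("criterion shifts move beta0 but not Target coefficients", {
  cells <- data.frame(cell = c("a", "b"))
  t1 <- make_count_table(cells, c(100, 100), c(80, 70), c(100, 100),
                         c(20, 30))
  # same d' per cell, all rates shifted by a common criterion change
  shift_counts <- function(h, f) {
    z <- qnorm(h / 100) - 0.4
    zf <- qnorm(f / 100) - 0.4
    c(round(pnorm(z) * 100), round(pnorm(zf) * 100))
  }
  h_a <- shift_counts(80, 20); h_b <- shift_counts(70, 30)
  t2 <- make_count_table(cells, c(100, 100), c(h_a[1], h_b[1]),
                         c(100, 100), c(h_a[2], h_b[2]))
  f1 <- fit_probit(sdt_design(t1, "cell"))
  f2 <- fit_probit(sdt_design(t2, "cell"))
  # rounding the shifted counts moves rates slightly; d' must stay put
  expect_equal(unname(coef(f1)["Target"]), unname(coef(f2)["Target"]),
               tolerance = 0.03)
  expect_gt(coef(f2)["Criterion"], coef(f1)["Criterion"] + 0.3)
})

test_that("mixed probit reduces to fixed fit at zero variance and matches lme4", {
  p <- observer_params(subject_sd_dprime = 0, subject_sd_criterion = 0)
  tab <- quick_cohort(6, seed = 31, shift_ms = 5, n_blocks = 3, params = p)
  des <- sdt_design(tab, "temporal_condition")
  fx <- fit_probit(des)
  mx <- fit_probit_mixed(des)
  expect_lt(mx$sigma_subject, 0.05)
  expect_equal(unname(coef(mx)), unname(coef(fx)), tolerance = 1e-3)

  ph <- observer_params(subject_sd_dprime = 0.3, subject_sd_criterion = 0.3)
  tabh <- quick_cohort(8, seed = 33, shift_ms = 5, n_blocks = 3, params = ph)
  desh <- sdt_design(tabh, "temporal_condition")
  mh <- fit_probit_mixed(desh)
  df <- data.frame(y = desh$y, desh$X[, -1], subject = desh$subject,
                   check.names = FALSE)
  gm <- lme4::glmer(y ~ . - subject + (1 | subject), data = df,
                    family = stats::binomial("probit"))
  expect_equal(unname(coef(mh)[-1]), unname(lme4::fixef(gm)[-1]),
               tolerance = 1e-3)
  expect_equal(mh$sigma_subject,
               sqrt(unname(unlist(lme4::VarCorr(gm)))), tolerance = 1e-3)
  expect_gt(mh$sigma_subject, 0.1)
  expect_error(fit_probit_mixed(sdt_design(tab[tab$subject == 1, ],
                                           "temporal_condition")),
               ">= 2 subjects")
})

test_that("contrast runs Wald F tests on coefficient combinations", {
  cells <- data.frame(temporal_condition = c("aperiodic", "periodic"))
  tab <- make_count_table(cells, c(200, 200), c(140, 170), c(100, 100),
                          c(30, 20))
  fit <- fit_probit(sdt_design(tab, "temporal_condition"))
  # zero weights: estimate 0, p = 1
  z <- contrast(fit, setNames(numeric(4), names(coef(fit))))
  expect_equal(z$estimate, 0)
  expect_equal(z$p, 1)
  # single coefficient contrast equals the coefficient
  w <- setNames(c(0, 0, 0, 1), names(coef(fit)))
  ct <- contrast(fit, w)
  expect_equal(ct$estimate,
               unname(coef(fit)["Target:temporal_conditionperiodic"]))
  expect_equal(ct$df1, 1)
  expect_lt(ct$p, 0.05)
  # named partial weight vector and character pair agree
  ct2 <- contrast(fit, c("Target:temporal_conditionperiodic" = 1))
  expect_error(contrast(fit, c(nonsense = 1)), "absent")
  pair <- contrast(fit, c("Target", "Criterion"))
  expect_equal(pair$estimate,
               unname(coef(fit)["Target"] - coef(fit)["Criterion"]))
})

test_that("lr_test compares nested fits and rejects non-nested input", {
  tab <- quick_cohort(4, seed = 35, shift_ms = 5, n_blocks = 2)
  full_des <- sdt_design(tab, "temporal_condition")
  full <- fit_probit(full_des)
  red_des <- full_des
  red_des$X <- full_des$X[, !grepl("^Target:", colnames(full_des$X)),
                          drop = FALSE]
  red <- fit_probit(red_des)
  lt <- lr_test(full, red)
  expect_equal(lt$df, 2)
  expect_gte(lt$statistic, 0)
  same <- lr_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(lr_test(red, full), "nested")
})

test_that("bonferroni caps and preserves order", {
  expect_equal(bonferroni(0.01, m = 6), 0.06)
  expect_equal(bonferroni(0.5, m = 3), 1)
  p <- c(0.001, 0.04, 0.2, 0.01)
  expect_equal(order(bonferroni(p)), order(p))
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "at least")
})

test_that("bootstrap_dprime_ci resamples at the subject level", {
  cells <- data.frame(temporal_condition = c("aperiodic", "periodic"))
  one <- function(s) make_count_table(cells, c(40, 40), c(28, 34),
                                      c(20, 20), c(6, 3), subject = s)
  tab <- do.call(rbind, lapply(1:8, one))  # identical subjects
  ci <- bootstrap_dprime_ci(tab, "temporal_condition", n_boot = 200,
                            seed = 1)
  expect_equal(nrow(ci), 2)
  # all subjects identical -> zero-width interval at the point estimate
  expect_equal(ci$ci_lower, ci$estimate)
  expect_equal(ci$ci_upper, ci$estimate)
  expect_equal(ci$boot_mean, ci$estimate)
  d_exp <- dprime_classic(28 / 40, 6 / 20, "loglinear", 40, 20)
  expect_equal(ci$estimate[ci$temporal_condition == "aperiodic"], d_exp)

  expect_warning(bootstrap_dprime_ci(one(1), "temporal_condition",
                                     n_boot = 50, seed = 1), "single")
  # determinism
  tabh <- quick_cohort(5, seed = 40, shift_ms = 5, n_blocks = 2)
  c1 <- bootstrap_dprime_ci(tabh, "temporal_condition", n_boot = 100,
                            seed = 3)
  expect_identical(c1, bootstrap_dprime_ci(tabh, "temporal_condition",
                                           n_boot = 100, seed = 3))
  expect_true(all(c1$ci_lower <= c1$boot_mean & c1$boot_mean <= c1$ci_upper))
})

test_that("logrt_summary averages natural-log RTs of correct trials", {
  tab <- data.frame(subject = rep(1:2, each = 6), block = 1L,
                    phase = "main",
                    temporal_condition = rep(c("aperiodic", "periodic"), 6),
                    target_present = TRUE,
                    response = rep(c("yes", "yes", "no"), 4),
                    rt_s = rep(c(0.5, 0.8, NA), 4))
  tab$correct <- tab$response == "yes"
  out <- logrt_summary(tab, "temporal_condition")
  expect_equal(nrow(out), 4)
  expect_true(all(out$n_correct == 2))
  # constant RT r within a cell -> ln(r)
  tabc <- tab; tabc$rt_s[tabc$response == "yes"] <- 0.63
  outc <- logrt_summary(tabc, "temporal_condition")
  expect_equal(outc$mean_logrt, rep(log(0.63), 4))
  # cells without correct trials are flagged NA
  tabn <- tab
  tabn$response[tabn$subject == 2 &
                  tabn$temporal_condition == "periodic"] <- "no"
  tabn$correct <- tabn$response == "yes"
  tabn$rt_s[tabn$response == "no"] <- NA
  expect_warning(outn <- logrt_summary(tabn, "temporal_condition"),
                 "no correct")
  expect_true(is.na(outn$mean_logrt[outn$subject == 2 &
                                      outn$temporal_condition == "periodic"]))
})
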