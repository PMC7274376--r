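#' Trial-log schema
#'
#' The ordered column set of the plain-CSV trial log exchanged between
#' the simulator, the stimulus renderer and the analysis: one row per
#' trial, header exactly as listed, missing RTs written as empty fields.
#'
#' @return Character vector of column names.
#' @export
trial_log_columns <- function() {
  c("subject", "block", "phase", "variant", "temporal_condition",
    "rate_hz", "carrier_hz", "target_present", "target_index", "shift_ms",
    "response", "correct", "rt_s", "seed")
}

#' Write a trial log as CSV
#'
#' @param table Trial-log data frame (extra columns are dropped; the
#'   schema columns must all be present).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(table, path) {
  cols <- trial_log_columns()
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stop("trial log lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  write.csv(table[cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trial log CSV
#'
#' Validates the header against [trial_log_columns()] and restores
#' column types (losslessly round-tripping [write_trial_log()] output).
#'
#' @param path CSV path.
#' @return Trial-log data frame.
#' @export
read_trial_log <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(subject = "integer", block = "integer",
                                 phase = "character", variant = "character",
                                 temporal_condition = "character",
                                 rate_hz = "numeric", carrier_hz = "numeric",
                                 target_present = "logical",
                                 target_index = "integer",
                                 shift_ms = "numeric",
                                 response = "character",
                                 correct = "logical", rt_s = "numeric",
                                 seed = "integer"))
  if (!identical(names(tab), trial_log_columns()))
    stop("trial-log header does not match the schema", call. = FALSE)
  tab
}

variant_presets <- function(variant) {
  switch(variant,
         "1a" = , "1b" = list(rates = c(1, 2, 4, 8),
                              carriers = c(200, 1100, 3100),
                              total_duration_s = 12, shift_ms = 6,
                              n_trials = 480,
                              conditions = "periodic"),
         "2" = list(rates = 2, carriers = 1100, total_duration_s = 6,
                    shift_ms = NA_real_, n_trials = 432,
                    conditions = c("periodic", "aperiodic", "cue")),
         "pilot" = list(rates = c(1, 2), carriers = 1100,
                        total_duration_s = 12, shift_ms = 6, n_trials = 80,
                        conditions = "aperiodic"),
         stop("unknown variant: ", variant, call. = FALSE))
}

#' Load and validate a run configuration
#'
#' Reads a JSON configuration file. Required keys: `variant` (one of
#' `"1a"`, `"1b"`, `"2"`, `"pilot"`) and `seed` (runs must be
#' reproducible). Optional keys: `n_subjects`, `shift_ms`, `n_boot`,
#' `alpha`, `observer` (a named list overriding [observer_params()]
#' arguments). Unknown keys are rejected. Variant presets (rates,
#' carriers, durations, trial counts) are filled in automatically.
#'
#' @param path Path to a JSON file.
#' @return An object of class `run_config`.
#' @export
load_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("variant", "seed", "n_subjects", "shift_ms", "n_boot",
               "alpha", "observer")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$variant))
    stop("config must set `variant`", call. = FALSE)
  cfg$variant <- as.character(cfg$variant)
  if (!cfg$variant %in% c("1a", "1b", "2", "pilot"))
    stop("`variant` must be one of 1a, 1b, 2, pilot", call. = FALSE)
  if (is.null(cfg$seed))
    stop("config must set `seed` (reproducibility required)", call. = FALSE)
  preset <- variant_presets(cfg$variant)
  cfg$n_subjects <- cfg$n_subjects %||% 1L
  cfg$shift_ms <- cfg$shift_ms %||% preset$shift_ms
  cfg$n_boot <- cfg$n_boot %||% 1000L
  cfg$alpha <- cfg$alpha %||% 0.05
  cfg$observer <- do.call(observer_params, as.list(cfg$observer %||% list()))
  cfg$preset <- preset
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> variant %s, %d subject(s), seed %s\n",
              x$variant, x$n_subjects, format(x$seed)))
  invisible(x)
}

#' Analyze a trial log
#'
#' The study's analysis pipeline on one trial log: per-cell bootstrap d'
#' estimates, probit-GLM condition contrasts with Bonferroni correction,
#' a likelihood-ratio test of the condition effect on d', and (when RTs
#' are present) per-subject correct-trial log-RT summaries with OLS
#' contrasts.
#'
#' @param table Trial-log data frame (main-phase rows are analyzed).
#' @param factors Condition columns to analyze; defaults to
#'   `"temporal_condition"` when it varies, otherwise the varying ones
#'   among `rate_hz`, `carrier_hz`.
#' @param n_boot Bootstrap resamples for the d' CIs.
#' @param seed Optional integer seed for the bootstrap.
#' @return List of class `tempshift_analysis`: `dprime` (a `dprime_ci`
#'   table), `fit` (full probit fit), `lr` (condition LR test),
#'   `contrasts` (pairwise Target-interaction contrasts, Bonferroni
#'   adjusted), `logrt` (per-subject means), `logrt_contrasts`.
#' @export
analyze_dataset <- function(table, factors = NULL, n_boot = 1000,
                            seed = NULL) {
  tab <- table[table$phase == "main", , drop = FALSE]
  if (is.null(factors)) {
    cand <- c("temporal_condition", "rate_hz", "carrier_hz")
    factors <- cand[vapply(cand, function(f)
      length(unique(tab[[f]])) > 1, logical(1))]
    if (!length(factors)) factors <- "temporal_condition"
  }
  dp <- bootstrap_dprime_ci(tab, factors, n_boot = n_boot, seed = seed)
  des_full <- sdt_design(tab, factors)
  fit <- fit_probit(des_full)
  # reduced model: drop every Target x condition interaction
  keep <- !grepl("^Target:", colnames(des_full$X))
  des_red <- des_full
  des_red$X <- des_full$X[, keep, drop = FALSE]
  lr <- lr_test(fit, fit_probit(des_red))
  inter <- grep("^Target:", names(fit$coefficients), value = TRUE)
  ctr <- NULL
  if (length(inter)) {
    pairs_ <- c(lapply(inter, function(nm) setNames(1, nm)),
                if (length(inter) >= 2)
                  utils::combn(inter, 2, simplify = FALSE,
                               FUN = function(p) setNames(c(1, -1), p)))
    ctr <- do.call(rbind, lapply(pairs_, function(w) {
      W <- matrix(w, nrow = 1, dimnames = list(NULL, names(w)))
      cbind(contrast = paste(names(w)[w != 0], collapse = " - "),
            contrast(fit, W))
    }))
    ctr$p_adj <- bonferroni(ctr$p, nrow(ctr))
  }
  logrt <- NULL; logrt_ctr <- NULL
  if (any(tab$correct & tab$target_present & !is.na(tab$rt_s))) {
    logrt <- suppressWarnings(logrt_summary(tab, factors))
    ok <- !is.na(logrt$mean_logrt)
    if (length(factors) && nrow(unique(logrt[ok, factors, drop = FALSE])) > 1) {
      fl <- logrt[ok, , drop = FALSE]
      for (f in factors) {
        v <- factor(as.character(fl[[f]]))
        ref <- c(rate_hz = "1", carrier_hz = "1100",
                 temporal_condition = "aperiodic")[f]
        if (!is.na(ref) && ref %in% levels(v)) v <- stats::relevel(v, ref)
        fl[[f]] <- v
      }
      lmfit <- stats::lm(stats::as.formula(
        paste("mean_logrt ~", paste(factors, collapse = " * "))), data = fl)
      sm <- summary(lmfit)$coefficients
      logrt_ctr <- data.frame(term = rownames(sm), estimate = sm[, 1],
                              se = sm[, 2], t = sm[, 3], p = sm[, 4],
                              row.names = NULL)
    }
  }
  structure(list(dprime = dp, fit = fit, lr = lr, contrasts = ctr,
                 logrt = logrt, logrt_contrasts = logrt_ctr,
                 factors = factors),
            class = "tempshift_analysis")
}

#' @export
print.tempshift_analysis <- function(x, ...) {
  cat("Per-cell d' (subject-level bootstrap 95% CI):\n")
  print(cbind(x$dprime[x$factors],
              round(x$dprime[c("estimate", "ci_lower", "ci_upper")], 3)))
  cat(sprintf("\nCondition effect on d': LR chi2(%d) = %.2f, p = %.3g\n",
              x$lr$df, x$lr$statistic, x$lr$p))
  if (!is.null(x$contrasts)) {
    cat("\nPlanned contrasts (d' scale, Bonferroni adjusted):\n")
    print(cbind(x$contrasts["contrast"],
                round(x$contrasts[c("estimate", "F", "p", "p_adj")], 4)))
  }
  if (!is.null(x$logrt_contrasts)) {
    cat("\nlogRT model (per-subject means of correct trials):\n")
    print(cbind(x$logrt_contrasts["term"],
                round(x$logrt_contrasts[c("estimate", "se", "p")], 4)))
  }
  invisible(x)
}

write_manifest <- function(path, cfg_path, seed, outputs) {
  lines <- c(
    paste0("package: tempshift ", as.character(packageVersion("tempshift"))),
    paste0("r_version: ", R.version.string),
    paste0("config: ", cfg_path %||% "(none)"),
    paste0("config_md5: ", if (!is.null(cfg_path))
      unname(tools::md5sum(cfg_path)) else ""),
    paste0("seed: ", seed),
    paste0("outputs: ", paste(outputs, collapse = ", ")))
  writeLines(lines, path)
  invisible(path)
}

cli_usage <- function() {
  paste(
    "usage: tempshift <subcommand> [--flag value ...]",
    "subcommands:",
    "  synth      --config FILE --out DIR           render example WAV stimuli",
    "  simulate   --variant V --subjects N --seed S --out FILE.csv",
    "  staircase  --seed S --out FILE.csv           run one adaptive track",
    "  analyze    --in FILE.csv --outdir DIR [--seed S]",
    "  reproduce  --variant V --subjects N --seed S [--outdir DIR]",
    sep = "\n")
}

parse_flags <- function(argv) {
  flags <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--") || i == length(argv))
      stop("malformed flag: ", a, call. = FALSE)
    flags[[substring(a, 3)]] <- argv[i + 1L]
    i <- i + 2L
  }
  flags
}

#' Command-line entry point
#'
#' Dispatches the package's subcommands (see `cli(character(0))` for
#' usage): `synth` renders WAV stimuli for a config, `simulate` writes a
#' cohort trial log, `staircase` runs one adaptive track, `analyze`
#' ingests a trial log and writes d'/contrast/log-RT tables, `reproduce`
#' chains simulate and analyze with the study-default effect sizes and
#' prints the recovered contrasts. Each run writes a plain-text manifest
#' beside its outputs.
#'
#' Invoke from a shell as
#' `Rscript -e 'quit(status = tempshift::cli())'` with arguments after
#' `--args`.
#'
#' @param argv Character vector of arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly (0 on success).
#' @export
cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) {
    message(cli_usage())
    return(invisible(1L))
  }
  sub <- argv[1]
  ok <- tryCatch({
    flags <- parse_flags(argv[-1])
    switch(sub,
           synth = cli_synth(flags),
           simulate = cli_simulate(flags),
           staircase = cli_staircase(flags),
           analyze = cli_analyze(flags),
           reproduce = cli_reproduce(flags),
           stop("unknown subcommand: ", sub, call. = FALSE))
    TRUE
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    message(cli_usage())
    FALSE
  })
  invisible(if (ok) 0L else 1L)
}

need_flag <- function(flags, name) {
  if (is.null(flags[[name]]))
    stop("missing required flag --", name, call. = FALSE)
  flags[[name]]
}

cli_synth <- function(flags) {
  cfg <- load_config(need_flag(flags, "config"))
  out <- need_flag(flags, "out")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  preset <- cfg$preset
  seeds <- spawn_seeds(cfg$seed, length(preset$conditions) *
                         length(preset$rates) * length(preset$carriers) * 2)
  k <- 0L
  files <- character(0)
  shift <- if (is.na(cfg$shift_ms)) 4 else cfg$shift_ms
  for (cond in preset$conditions) for (rate in preset$rates)
    for (carrier in preset$carriers) for (target in c(FALSE, TRUE)) {
      k <- k + 1L
      timing <- switch(cond,
        periodic = periodic_timing(rate, preset$total_duration_s,
                                   if (target) 9L else NA,
                                   if (target) shift else 0),
        aperiodic = aperiodic_timing(rate, preset$total_duration_s,
                                     if (target) 9L else NA,
                                     if (target) shift else 0,
                                     seed = seeds[k]),
        cue = cue_timing(500, if (target) shift else 0))
      wave <- render_sequence(timing, carrier_spec(carrier), seed = seeds[k])
      f <- file.path(out, sprintf("%s_%ghz_%ghz_%s.wav", cond, rate,
                                  carrier, if (target) "target" else "catch"))
      write_audio(wave, f)
      files <- c(files, f)
    }
  write_manifest(file.path(out, "manifest.txt"), flags$config, cfg$seed,
                 basename(files))
  message("wrote ", length(files), " WAV files to ", out)
}

cli_simulate <- function(flags) {
  variant <- need_flag(flags, "variant")
  seed <- as.integer(need_flag(flags, "seed"))
  n_subj <- as.integer(flags$subjects %||% 1L)
  out <- need_flag(flags, "out")
  seeds <- spawn_seeds(seed, 2)
  plan <- build_session(variant, n_subj, seed = seeds[1])
  tab <- simulate_dataset(observer_params(), plan, seed = seeds[2])
  tab$seed <- seed
  write_trial_log(tab, out)
  write_manifest(paste0(out, ".manifest.txt"), NULL, seed, out)
  message("wrote ", nrow(tab), " trials to ", out)
}

cli_staircase <- function(flags) {
  seed <- as.integer(need_flag(flags, "seed"))
  out <- need_flag(flags, "out")
  params <- observer_params()
  obs <- function(level_ms) {
    d <- cell_dprime(params, level_ms, 2, 1100, "aperiodic", NA)
    runif(1) < pnorm(d / 2 - params$criterion)
  }
  res <- run_staircase(obs, seed = seed)
  tr <- res$trace
  log <- data.frame(subject = 1L, block = 1L, phase = "staircase",
                    variant = "2", temporal_condition = "aperiodic",
                    rate_hz = 2, carrier_hz = 1100, target_present = TRUE,
                    target_index = NA_integer_, shift_ms = tr$level_ms,
                    response = ifelse(tr$correct, "yes", "no"),
                    correct = tr$correct, rt_s = NA_real_, seed = seed)
  write_trial_log(log, out)
  message(sprintf("staircase: %d trials, %d reversals, threshold %.2f ms",
                  nrow(tr), length(res$state$reversal_levels),
                  res$threshold))
}

cli_analyze <- function(flags) {
  tab <- read_trial_log(need_flag(flags, "in"))
  outdir <- flags$outdir %||% "."
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (!is.null(flags$seed)) as.integer(flags$seed) else NULL
  an <- analyze_dataset(tab, seed = seed)
  write.csv(an$dprime, file.path(outdir, "dprime_ci.csv"),
            row.names = FALSE)
  if (!is.null(an$contrasts))
    write.csv(an$contrasts, file.path(outdir, "contrasts.csv"),
              row.names = FALSE)
  if (!is.null(an$logrt))
    write.csv(an$logrt, file.path(outdir, "logrt.csv"), row.names = FALSE)
  if (!is.null(an$logrt_contrasts))
    write.csv(an$logrt_contrasts, file.path(outdir, "logrt_contrasts.csv"),
              row.names = FALSE)
  write_manifest(file.path(outdir, "manifest.txt"), NULL,
                 seed %||% NA, c("dprime_ci.csv", "contrasts.csv"))
  print(an)
}

cli_reproduce <- function(flags) {
  variant <- flags$variant %||% "2"
  seed <- as.integer(need_flag(flags, "seed"))
  n_subj <- as.integer(flags$subjects %||% 20L)
  seeds <- spawn_seeds(seed, 3)
  plan <- build_session(variant, n_subj, seed = seeds[1])
  tab <- simulate_dataset(observer_params(), plan, seed = seeds[2])
  an <- analyze_dataset(tab, seed = seeds[3])
  if (!is.null(flags$outdir)) {
    dir.create(flags$outdir, recursive = TRUE, showWarnings = FALSE)
    write_trial_log(tab, file.path(flags$outdir, "trials.csv"))
    write.csv(an$dprime, file.path(flags$outdir, "dprime_ci.csv"),
              row.names = FALSE)
    if (!is.null(an$contrasts))
      write.csv(an$contrasts, file.path(flags$outdir, "contrasts.csv"),
                row.names = FALSE)
    write_manifest(file.path(flags$outdir, "manifest.txt"), NULL, seed,
                   "trials.csv")
  }
  print(an)
}
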