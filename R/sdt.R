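#' Hit and false-alarm rates per design cell
#'
#' Counts "yes" responses conditional on target presence and absence
#' within each combination of the grouping columns.
#'
#' @param table Trial-log data frame (columns `target_present`,
#'   `response`, plus the grouping columns).
#' @param grouping Character vector of grouping column names (may be
#'   empty for a single pooled cell).
#' @return Data frame with one row per cell: grouping columns,
#'   `n_target`, `n_hit`, `n_catch`, `n_fa`, `hit`, `fa`. Cells without
#'   target (or catch) trials get `NA` rates with a warning.
#' @export
rates <- function(table, grouping = character()) {
  missing_cols <- setdiff(c(grouping, "target_present", "response"),
                          names(table))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  yes <- table$response == "yes"
  key <- if (length(grouping))
    interaction(table[grouping], drop = TRUE, lex.order = TRUE)
  else factor(rep("all", nrow(table)))
  agg <- function(v) as.vector(rowsum(as.numeric(v), key))
  cells <- if (length(grouping)) {
    u <- !duplicated(key)
    df <- table[u, grouping, drop = FALSE][order(key[u]), , drop = FALSE]
    rownames(df) <- NULL
    df
  } else data.frame(row.names = seq_along(levels(key)))
  out <- cbind(cells, data.frame(
    n_target = agg(table$target_present),
    n_hit = agg(yes & table$target_present),
    n_catch = agg(!table$target_present),
    n_fa = agg(yes & !table$target_present)))
  out$hit <- ifelse(out$n_target > 0, out$n_hit / out$n_target, NA_real_)
  out$fa <- ifelse(out$n_catch > 0, out$n_fa / out$n_catch, NA_real_)
  if (anyNA(out$hit) || anyNA(out$fa))
    warning("some cells lack target or catch trials; rates set to NA",
            call. = FALSE)
  out
}

#' Classical d' from hit and false-alarm rates
#'
#' `d' = qnorm(hit) - qnorm(fa)`. With `correction = "loglinear"` the
#' rates are recomputed from counts as `(count + 0.5) / (N + 1)` before
#' the z-transform, keeping extreme rates (0 or 1) finite.
#'
#' @param hit,fa Rates in `[0, 1]` (vectorized).
#' @param correction `"none"` or `"loglinear"`.
#' @param n_target,n_catch Trial counts per cell, required for the
#'   log-linear correction.
#' @return d' values (probit scale).
#' @examples
#' dprime_classic(0.9, 0.1)  # 2.5631
#' @export
dprime_classic <- function(hit, fa, correction = c("none", "loglinear"),
                           n_target = NULL, n_catch = NULL) {
  correction <- match.arg(correction)
  if (any(hit < 0 | hit > 1 | fa < 0 | fa > 1, na.rm = TRUE))
    stop("rates must lie in [0, 1]", call. = FALSE)
  if (correction == "loglinear") {
    if (is.null(n_target) || is.null(n_catch))
      stop("log-linear correction needs `n_target` and `n_catch`",
           call. = FALSE)
    hit <- (hit * n_target + 0.5) / (n_target + 1)
    fa <- (fa * n_catch + 0.5) / (n_catch + 1)
  } else if (any(hit %in% c(0, 1) | fa %in% c(0, 1))) {
    stop("hit or false-alarm rate of 0/1 gives infinite d'; use ",
         "correction = \"loglinear\"", call. = FALSE)
  }
  qnorm(hit) - qnorm(fa)
}

#' Probit design matrix for SDT regression
#'
#' Builds the yes/no response vector and design matrix of the study's
#' probit formulation: a constant `Criterion` column coded -1 (so its
#' coefficient is interpretable as the criterion), a `Target` indicator
#' (1 = signal present), dummy-coded condition columns, and all
#' `Target x condition` interactions, which carry the d' differences.
#' Reference levels are 1 Hz, 1100 Hz and `aperiodic` where those factors
#' appear.
#'
#' @param table Trial-log data frame.
#' @param factors Character vector of condition columns to cross with
#'   `Target` (e.g. `"temporal_condition"`, `c("rate_hz", "carrier_hz")`).
#' @return List of class `sdt_design`: `y` (0/1), `X`, `subject`,
#'   `factors`, `table_n`.
#' @export
sdt_design <- function(table, factors = character()) {
  stopifnot(all(c("response", "target_present") %in% names(table)))
  y <- as.integer(table$response == "yes")
  df <- data.frame(Target = as.integer(table$target_present))
  ref_levels <- c(rate_hz = "1", carrier_hz = "1100",
                  temporal_condition = "aperiodic")
  for (f in factors) {
    if (!f %in% names(table)) stop("no column ", f, call. = FALSE)
    v <- factor(as.character(table[[f]]))
    ref <- ref_levels[f]
    if (!is.na(ref) && ref %in% levels(v)) v <- stats::relevel(v, ref)
    df[[f]] <- v
  }
  form <- if (length(factors))
    stats::as.formula(paste("~ Target *", paste(factors, collapse = " * ")))
  else ~Target
  X <- model.matrix(form, df)
  X[, 1] <- -1
  colnames(X)[1] <- "Criterion"
  structure(list(y = y, X = X,
                 subject = if ("subject" %in% names(table))
                   factor(table$subject) else NULL,
                 factors = factors, table_n = nrow(table)),
            class = "sdt_design")
}

probit_loglik <- function(y, eta) {
  p <- pnorm(eta)
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Maximum-likelihood probit regression (IRLS)
#'
#' Fits the binary probit model by iteratively reweighted least squares.
#' On a saturated single-cell SDT design the coefficients reproduce the
#' classical estimator exactly: `Criterion = -qnorm(fa)` (equivalently
#' the intercept under +1 coding is `qnorm(fa)`) and
#' `Target = qnorm(hit) - qnorm(fa) = d'`.
#'
#' @param design An [sdt_design()], or a list with elements `y` and `X`.
#' @param tol Convergence tolerance on the deviance (default 1e-12).
#' @param max_iter Iteration cap (default 100).
#' @return An object of class `probit_fit`: `coefficients`, `vcov`,
#'   `logLik`, `deviance`, `fitted`, `df_residual`, `converged`, `iter`,
#'   `y`, `X`.
#' @export
fit_probit <- function(design, tol = 1e-12, max_iter = 100) {
  y <- design$y; X <- design$X
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("design matrix is rank deficient (", qrX$rank, " < ", ncol(X),
         "); drop aliased columns", call. = FALSE)
  n <- length(y); p <- ncol(X)
  beta <- numeric(p)
  dev_old <- Inf
  converged <- FALSE
  eps <- 1e-10
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- pmin(pmax(pnorm(eta), eps), 1 - eps)
    dens <- pmax(dnorm(eta), eps)
    w <- dens^2 / (mu * (1 - mu))
    z <- eta + (y - mu) / dens
    fit <- lm.wfit(X, z, w)
    beta <- fit$coefficients
    dev <- -2 * probit_loglik(y, drop(X %*% beta))
    if (!is.finite(dev)) break
    if (abs(dev - dev_old) < tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  eta <- drop(X %*% beta)
  if (max(abs(eta)) > 7)
    stop("probit fit diverged: some cells are perfectly separated ",
         "(fitted probabilities of 0/1) -- aggregate cells or use ",
         "dprime_classic() with correction = \"loglinear\"", call. = FALSE)
  mu <- pmin(pmax(pnorm(eta), eps), 1 - eps)
  dens <- dnorm(eta)
  w <- dens^2 / (mu * (1 - mu))
  XtWX <- crossprod(X * sqrt(w))
  vcov <- tryCatch(solve(XtWX), error = function(e)
    matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X))))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  ll <- probit_loglik(y, eta)
  structure(list(coefficients = setNames(beta, colnames(X)), vcov = vcov,
                 logLik = ll, deviance = -2 * ll, fitted = mu,
                 df_residual = n - p, n = n, converged = converged,
                 iter = it, y = y, X = X, sigma_subject = NULL),
            class = "probit_fit")
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf("<probit_fit> n = %d, logLik = %.3f%s\n", x$n, x$logLik,
              if (!is.null(x$sigma_subject))
                sprintf(", subject SD = %.3f", x$sigma_subject) else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.probit_fit <- function(object, ...) object$coefficients

#' @export
vcov.probit_fit <- function(object, ...) object$vcov

#' @export
logLik.probit_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients) +
              !is.null(object$sigma_subject), class = "logLik")
}

# Profile the subject random intercepts: one-dimensional Newton (Fisher
# scoring) per subject for fixed beta and sigma. Returns the Laplace
# log-likelihood and the conditional modes.
laplace_loglik <- function(theta, y, X, subject_idx, n_subj) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  sigma <- exp(theta[p + 1])
  eta_fix <- drop(X %*% beta)
  b <- numeric(n_subj)
  eps <- 1e-10
  for (it in 1:25) {
    eta <- eta_fix + b[subject_idx]
    mu <- pmin(pmax(pnorm(eta), eps), 1 - eps)
    dens <- pmax(dnorm(eta), eps)
    score_i <- rowsum(dens * (y - mu) / (mu * (1 - mu)), subject_idx)
    info_i <- rowsum(dens^2 / (mu * (1 - mu)), subject_idx)
    step <- (score_i - b / sigma^2) / (info_i + 1 / sigma^2)
    b <- b + drop(step)
    if (max(abs(step)) < 1e-10) break
  }
  eta <- eta_fix + b[subject_idx]
  mu <- pmin(pmax(pnorm(eta), eps), 1 - eps)
  dens <- pmax(dnorm(eta), eps)
  info_i <- drop(rowsum(dens^2 / (mu * (1 - mu)), subject_idx))
  ll <- probit_loglik(y, eta) - sum(b^2) / (2 * sigma^2) -
    0.5 * sum(log1p(sigma^2 * info_i))
  list(ll = ll, b = b)
}

#' Probit regression with a subject random intercept
#'
#' The mixed extension of [fit_probit()]: a normal random intercept per
#' subject, fitted by Laplace-approximated maximum likelihood (inner
#' Newton profiling of the subject modes, outer quasi-Newton over the
#' fixed effects and the log random-intercept SD). With an estimated
#' subject SD of (near) zero the fixed effects reduce to the ordinary
#' probit fit.
#'
#' @param design An [sdt_design()] carrying a `subject` factor (>= 2
#'   subjects).
#' @param start_sd Starting value for the subject SD (default 0.3).
#' @return A `probit_fit` with `sigma_subject` (estimated SD) and
#'   `ranef` (conditional subject modes).
#' @export
fit_probit_mixed <- function(design, start_sd = 0.3) {
  if (is.null(design$subject) || nlevels(design$subject) < 2L)
    stop("mixed fit needs a subject factor with >= 2 subjects",
         call. = FALSE)
  y <- design$y; X <- design$X
  subject_idx <- as.integer(design$subject)
  n_subj <- nlevels(design$subject)
  init <- fit_probit(design)
  theta0 <- c(init$coefficients, log(start_sd))
  negll <- function(th) -laplace_loglik(th, y, X, subject_idx, n_subj)$ll
  opt <- optim(theta0, negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10), hessian = TRUE)
  if (opt$convergence != 0)
    stop("mixed probit fit did not converge (optim code ",
         opt$convergence, ")", call. = FALSE)
  p <- ncol(X)
  beta <- setNames(opt$par[seq_len(p)], colnames(X))
  sigma <- unname(exp(opt$par[p + 1]))
  vcov <- tryCatch(solve(opt$hessian)[seq_len(p), seq_len(p), drop = FALSE],
                   error = function(e) matrix(NA_real_, p, p))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  la <- laplace_loglik(opt$par, y, X, subject_idx, n_subj)
  eta <- drop(X %*% beta) + la$b[subject_idx]
  structure(list(coefficients = beta, vcov = vcov, logLik = -opt$value,
                 deviance = 2 * opt$value, fitted = pnorm(eta),
                 df_residual = length(y) - p - 1, n = length(y),
                 converged = TRUE, iter = NA_integer_, y = y, X = X,
                 sigma_subject = sigma,
                 ranef = setNames(la$b, levels(design$subject))),
            class = "probit_fit")
}

#' Wald F-test of a linear contrast
#'
#' Tests `w' beta = 0` (or `W beta = 0` for a contrast matrix) with a
#' Wald-type F statistic, `F = (w'b)^2 / (w' V w)` on 1 and residual
#' degrees of freedom. Estimates are reported in the units of the fitted
#' scale (d' for Target interactions of a probit fit, log-RT for linear
#' RT fits). For a pair of coefficient names the contrast is their
#' difference (first minus second).
#'
#' @param fit A `probit_fit` (or any list with `coefficients`, `vcov`,
#'   `df_residual`).
#' @param weights Named/numeric weight vector conformable with the
#'   coefficients, a contrast matrix (rows = contrasts), or a character
#'   pair of coefficient names.
#' @return Data frame with `estimate`, `F`, `df1`, `df2`, `p`.
#' @export
contrast <- function(fit, weights) {
  beta <- fit$coefficients
  V <- fit$vcov
  if (is.character(weights)) {
    if (length(weights) != 2L || !all(weights %in% names(beta)))
      stop("character `weights` must name two coefficients", call. = FALSE)
    w <- setNames(numeric(length(beta)), names(beta))
    w[weights[1]] <- 1; w[weights[2]] <- -1
    weights <- w
  }
  W <- if (is.matrix(weights)) weights
       else matrix(weights, nrow = 1,
                   dimnames = list(NULL, names(weights)))
  if (ncol(W) != length(beta)) {
    if (!is.null(colnames(W)) && all(colnames(W) %in% names(beta))) {
      full <- matrix(0, nrow(W), length(beta),
                     dimnames = list(NULL, names(beta)))
      full[, colnames(W)] <- W
      W <- full
    } else stop("contrast weights touch absent coefficients", call. = FALSE)
  }
  est <- drop(W %*% beta)
  q <- qr(W)$rank
  if (q == 0 || all(W == 0)) {
    return(data.frame(estimate = if (nrow(W) == 1) 0 else NA_real_,
                      F = 0, df1 = 0, df2 = fit$df_residual, p = 1))
  }
  Fstat <- drop(t(est) %*% solve(W %*% V %*% t(W), est)) / q
  data.frame(estimate = if (nrow(W) == 1) est else NA_real_,
             F = Fstat, df1 = q, df2 = fit$df_residual,
             p = pf(Fstat, q, fit$df_residual, lower.tail = FALSE))
}

#' Likelihood-ratio test of nested probit fits
#'
#' `2 (logLik_full - logLik_reduced)` against a chi-square with degrees
#' of freedom equal to the parameter-count difference.
#'
#' @param fit_full,fit_reduced Nested `probit_fit` objects on the same
#'   data (identical row count; the reduced model's columns a subset of
#'   the full model's).
#' @return Data frame with `statistic`, `df`, `p`.
#' @export
lr_test <- function(fit_full, fit_reduced) {
  if (fit_full$n != fit_reduced$n)
    stop("models were fitted to different data", call. = FALSE)
  df <- length(fit_full$coefficients) - length(fit_reduced$coefficients)
  if (df < 0)
    stop("`fit_full` has fewer parameters than `fit_reduced`; not nested ",
         "in that order", call. = FALSE)
  if (!all(names(fit_reduced$coefficients) %in% names(fit_full$coefficients)))
    stop("reduced model terms are not a subset of the full model; ",
         "models are not nested", call. = FALSE)
  stat <- max(0, 2 * (fit_full$logLik - fit_reduced$logLik))
  data.frame(statistic = stat, df = df,
             p = if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE))
}

#' Bonferroni correction
#'
#' @param p Vector of p values.
#' @param m Number of comparisons in the family (`>= length(p)`;
#'   defaults to `length(p)`).
#' @return Adjusted p values, `min(1, m * p)`.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < length(p))
    stop("`m` must be at least the number of tests", call. = FALSE)
  pmin(1, m * p)
}

#' Per-subject classical d' by cell
#'
#' Log-linear-corrected classical d' computed within each
#' subject x grouping cell; the subject-level ingredient of the bootstrap.
#'
#' @inheritParams rates
#' @return Data frame: `subject`, grouping columns, counts, `dprime`.
#' @export
subject_dprime <- function(table, grouping) {
  r <- rates(table, c("subject", grouping))
  r$dprime <- dprime_classic(r$hit, r$fa, "loglinear",
                             n_target = r$n_target, n_catch = r$n_catch)
  r
}

#' Subject-level bootstrap confidence intervals for d'
#'
#' Computes each subject's classical d' per cell, then resamples subjects
#' with replacement (`n_boot` times, same cohort size) and takes the
#' cell-wise mean of the resampled subjects' d' values. Returns the
#' point estimate (cohort mean), bootstrap mean and percentile 95% CI.
#'
#' @inheritParams rates
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return Data frame of class `dprime_ci`: grouping columns, `estimate`,
#'   `boot_mean`, `ci_lower`, `ci_upper`, `n_subjects`.
#' @export
bootstrap_dprime_ci <- function(table, grouping, n_boot = 1000,
                                conf = 0.95, seed = NULL) {
  sd_ <- subject_dprime(table, grouping)
  subjects <- unique(sd_$subject)
  ns <- length(subjects)
  if (ns < 2L)
    warning("single subject: bootstrap CI is degenerate", call. = FALSE)
  # subjects x cells matrix of d'
  key_cell <- interaction(sd_[grouping], drop = TRUE, lex.order = TRUE)
  u <- !duplicated(key_cell)
  cells <- sd_[u, grouping, drop = FALSE][order(key_cell[u]), , drop = FALSE]
  rownames(cells) <- NULL
  mat <- matrix(NA_real_, ns, nlevels(key_cell),
                dimnames = list(subjects, levels(key_cell)))
  mat[cbind(match(sd_$subject, subjects), as.integer(key_cell))] <- sd_$dprime
  est <- colMeans(mat, na.rm = TRUE)
  boot <- with_seed(seed, {
    idx <- matrix(sample.int(ns, ns * n_boot, replace = TRUE), n_boot, ns)
    t(apply(idx, 1, function(i) colMeans(mat[i, , drop = FALSE],
                                         na.rm = TRUE)))
  })
  if (nlevels(key_cell) == 1L) boot <- matrix(boot, ncol = 1)
  alpha <- (1 - conf) / 2
  out <- cbind(cells, data.frame(
    estimate = est, boot_mean = colMeans(boot),
    ci_lower = apply(boot, 2, quantile, alpha),
    ci_upper = apply(boot, 2, quantile, 1 - alpha),
    n_subjects = ns))
  rownames(out) <- NULL
  class(out) <- c("dprime_ci", "data.frame")
  out
}

#' Per-subject mean log reaction time of correct trials
#'
#' Natural-log RTs (measured relative to target onset) of correct "yes"
#' responses, averaged within subject x cell. Incorrect trials and trials
#' without a response are excluded; cells with no correct target trials
#' yield `NA` with a warning.
#'
#' @inheritParams rates
#' @return Data frame: `subject`, grouping columns, `n_correct`,
#'   `mean_logrt`.
#' @export
logrt_summary <- function(table, grouping = character()) {
  keep <- table$target_present & table$correct &
    table$response == "yes" & !is.na(table$rt_s)
  sub <- table[keep, , drop = FALSE]
  if (!nrow(sub)) stop("no correct target trials with RTs", call. = FALSE)
  cols <- c("subject", grouping)
  got <- aggregate(list(mean_logrt = log(sub$rt_s)), by = sub[cols],
                   FUN = mean)
  got_n <- aggregate(list(n_correct = sub$rt_s), by = sub[cols],
                     FUN = length)
  # every subject x cell present in the trial log, so empty cells surface
  all_cells <- unique(table[cols])
  out <- merge(merge(all_cells, got_n, all.x = TRUE),
               got, all.x = TRUE, sort = TRUE)
  out$n_correct[is.na(out$n_correct)] <- 0L
  if (any(out$n_correct == 0))
    warning("some subject cells have no correct trials; mean_logrt NA",
            call. = FALSE)
  out <- out[do.call(order, out[cols]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
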