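# Performance measures with Monte Carlo standard errors. Each scalar
# measure takes the per-repetition values of ONE dgm-method cell and
# returns list(estimate, mcse); performance_table() assembles all cells.

ok_rows <- function(estimates) {
  estimates[!startsWith(estimates$status, "failed") &
              is.finite(estimates$estimate), , drop = FALSE]
}

#' Bias of the point estimates
#'
#' Mean point estimate minus the true estimand value, with Monte Carlo
#' standard error `sd(estimates)/sqrt(n)`.
#'
#' @param estimates Numeric vector of non-failed point estimates (one
#'   dgm-method cell; at least 2).
#' @param theta True estimand value.
#' @return `list(estimate, mcse)`.
#' @export
bias <- function(estimates, theta) {
  n <- length(estimates)
  if (n < 2L) stop("at least 2 estimates are needed", call. = FALSE)
  list(estimate = mean(estimates) - theta, mcse = sd(estimates) / sqrt(n))
}

#' Empirical standard error
#'
#' Standard deviation of the point estimates across repetitions -- the
#' actual precision of the method -- with Monte Carlo standard error
#' `empSE / sqrt(2 (n - 1))`.
#'
#' @inheritParams bias
#' @return `list(estimate, mcse)`.
#' @export
empirical_se <- function(estimates) {
  n <- length(estimates)
  if (n < 2L) stop("at least 2 estimates are needed", call. = FALSE)
  emp <- sd(estimates)
  list(estimate = emp, mcse = emp / sqrt(2 * (n - 1)))
}

#' Model-based standard error
#'
#' Root mean square of the per-repetition standard error estimates -- the
#' claimed precision -- with Monte Carlo standard error
#' `sqrt(var(se^2) / (4 n modSE^2))`. The root mean square (rather than the
#' plain mean) is used so that `modSE^2` unbiasedly estimates the mean
#' estimated variance.
#'
#' @param ses Numeric vector of non-failed standard error estimates (one
#'   cell; at least 2).
#' @return `list(estimate, mcse)`.
#' @export
model_se <- function(ses) {
  n <- length(ses)
  if (n < 2L) stop("at least 2 standard errors are needed", call. = FALSE)
  mod <- sqrt(mean(ses^2))
  mcse <- if (mod > 0) sqrt(var(ses^2) / (4 * n * mod^2)) else 0
  list(estimate = mod, mcse = mcse)
}

#' Relative error in the model-based standard error
#'
#' `100 * (modSE / empSE - 1)`, in percent: how far the claimed precision
#' is from the actual precision. The Monte Carlo standard error combines
#' the two components by the delta method, treating them as independent:
#' `100 * (modSE/empSE) * sqrt(mcse_mod^2/modSE^2 + 1/(2 (n-1)))`.
#'
#' @param mod_se,emp_se The two standard errors (scalars).
#' @param mod_se_mcse Monte Carlo SE of `mod_se`.
#' @param n_used Repetitions behind `emp_se`.
#' @return `list(estimate, mcse)`; `emp_se = 0` gives missing values.
#' @export
relative_error_mod_se <- function(mod_se, emp_se, mod_se_mcse, n_used) {
  if (!is.finite(emp_se) || emp_se <= 0) {
    return(list(estimate = NA_real_, mcse = NA_real_))
  }
  est <- 100 * (mod_se / emp_se - 1)
  mcse <- 100 * (mod_se / emp_se) *
    sqrt(mod_se_mcse^2 / mod_se^2 + 1 / (2 * (n_used - 1)))
  list(estimate = est, mcse = mcse)
}

#' Coverage of confidence intervals
#'
#' Percentage of intervals containing the true estimand value, with
#' binomial Monte Carlo standard error `100 * sqrt(p (1 - p) / n)`.
#'
#' @param ci_lows,ci_highs Interval bounds across repetitions (one cell).
#' @param theta True estimand value.
#' @return `list(estimate, mcse)`, both in percent.
#' @export
coverage <- function(ci_lows, ci_highs, theta) {
  n <- length(ci_lows)
  if (n < 1L) stop("at least 1 interval is needed", call. = FALSE)
  p <- mean(ci_lows <= theta & theta <= ci_highs)
  list(estimate = 100 * p, mcse = 100 * sqrt(p * (1 - p) / n))
}

#' Rejection rate of a Wald test
#'
#' Percentage of repetitions whose two-sided Wald p-value for
#' `H0: theta = theta0` falls below `alpha`. When the data are generated
#' under `theta = theta0` this is the type I error rate; generated under a
#' different value it is power -- interchanging the two is a classic
#' simulation mistake, so state which one a given run estimates.
#'
#' @param estimates,ses Per-repetition point estimates and standard
#'   errors.
#' @param dfs Degrees of freedom per repetition (recycled; `Inf` = Normal).
#' @param alpha Test size (default 0.05).
#' @param theta0 Null value (default 0).
#' @return `list(estimate, mcse)`, both in percent (binomial mcse).
#' @export
rejection_rate <- function(estimates, ses, dfs = Inf, alpha = 0.05,
                           theta0 = 0) {
  stopifnot(alpha > 0, alpha <= 1)
  n <- length(estimates)
  if (n < 1L) stop("at least 1 estimate is needed", call. = FALSE)
  dfs <- rep_len(dfs, n)
  stat <- abs(estimates - theta0) / ses
  pvals <- ifelse(is.finite(dfs), 2 * pt(-stat, df = dfs), 2 * pnorm(-stat))
  p <- mean(pvals < alpha)
  list(estimate = 100 * p, mcse = 100 * sqrt(p * (1 - p) / n))
}

#' Failure rate of a method
#'
#' Percentage and count of repetitions with a `failed:` status for one
#' dgm-method cell; backup invocations are counted separately. Failed
#' repetitions are excluded from the moment-based measures, so this count
#' is itself a performance measure -- a method that fails often is telling
#' you something.
#'
#' @param outcomes Analysis-outcome rows for one dgm-method cell.
#' @return `list(percent, count, n, n_backup)`.
#' @export
failure_rate <- function(outcomes) {
  n <- nrow(outcomes)
  cnt <- sum(startsWith(outcomes$status, "failed"))
  list(percent = if (n > 0) 100 * cnt / n else NA_real_, count = cnt,
       n = n, n_backup = sum(outcomes$backup_used))
}

perf_row <- function(dgm, method, measure, value, n_used, n_failed) {
  tibble::tibble(dgm = dgm, method = method, measure = measure,
                 estimate = value$estimate, mcse = value$mcse,
                 n_used = as.integer(n_used), n_failed = as.integer(n_failed))
}

#' Compute the full performance table
#'
#' All performance measures, for every dgm-method cell of an estimates
#' data set, each with its Monte Carlo standard error: bias, empirical and
#' model-based standard error, relative error in the model-based standard
#' error (percent), coverage (percent), rejection rate (percent; computed
#' as exclusion of `theta0` from the stored interval, equivalent to the
#' two-sided Wald test at the interval's degrees of freedom), failure rate
#' (percent) and outlier count under the default flagging rules. Failed
#' repetitions are excluded from the moment-based measures but counted.
#'
#' @param estimates An estimates tibble or a `sim_study`.
#' @param theta True estimand value (default 0).
#' @param theta0 Null value for the rejection rate (default `theta`).
#' @param outlier_rules Rules for the outlier count (see
#'   [flag_outliers()]).
#' @return A `performance_table` tibble: `dgm`, `method`, `measure`,
#'   `estimate`, `mcse`, `n_used`, `n_failed`.
#' @export
performance_table <- function(estimates, theta = 0, theta0 = theta,
                              outlier_rules = default_outlier_rules()) {
  if (inherits(estimates, "sim_study")) estimates <- estimates$estimates
  if (nrow(estimates) == 0L) stop("`estimates` is empty", call. = FALSE)
  cells <- dplyr::distinct(estimates, .data$dgm, .data$method)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- estimates[estimates$dgm == cells$dgm[i] &
                        estimates$method == cells$method[i], ]
    okc <- ok_rows(cell)
    n_used <- nrow(okc)
    n_failed <- nrow(cell) - n_used
    fr <- failure_rate(cell)
    flagged <- flag_outliers(cell, rules = outlier_rules)
    na_val <- list(estimate = NA_real_, mcse = NA_real_)
    if (n_used >= 2L) {
      b <- bias(okc$estimate, theta)
      e <- empirical_se(okc$estimate)
      m <- model_se(okc$se)
      r <- relative_error_mod_se(m$estimate, e$estimate, m$mcse, n_used)
      cv <- coverage(okc$ci_low, okc$ci_high, theta)
      rj <- coverage(okc$ci_low, okc$ci_high, theta0)
      rj <- list(estimate = 100 - rj$estimate, mcse = rj$mcse)
    } else {
      b <- e <- m <- r <- cv <- rj <- na_val
    }
    out[[i]] <- dplyr::bind_rows(
      perf_row(cells$dgm[i], cells$method[i], "bias", b, n_used, n_failed),
      perf_row(cells$dgm[i], cells$method[i], "emp_se", e, n_used, n_failed),
      perf_row(cells$dgm[i], cells$method[i], "mod_se", m, n_used, n_failed),
      perf_row(cells$dgm[i], cells$method[i], "rel_err_mod_se", r, n_used,
               n_failed),
      perf_row(cells$dgm[i], cells$method[i], "coverage", cv, n_used, n_failed),
      perf_row(cells$dgm[i], cells$method[i], "rejection_rate", rj, n_used,
               n_failed),
      perf_row(cells$dgm[i], cells$method[i], "failure_rate",
               list(estimate = fr$percent,
                    mcse = 100 * sqrt(fr$percent / 100 *
                                        (1 - fr$percent / 100) / fr$n)),
               n_used, n_failed),
      perf_row(cells$dgm[i], cells$method[i], "outlier_count",
               list(estimate = as.numeric(nrow(flagged$flagged)),
                    mcse = NA_real_),
               n_used, n_failed)
    )
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("performance_table", class(res))
  res
}

#' Format a performance table for the terminal
#'
#' Wide rendering -- measures by mechanism down the rows, methods across
#' the columns -- of the four headline measures.
#'
#' @param perf A [performance_table()].
#' @param digits Decimals for the standard-error-scale measures.
#' @return A character vector of lines (also printed by
#'   `print.performance_table`).
#' @export
format_performance <- function(perf, digits = 2) {
  measures <- c(bias = "Bias in point estimate",
                emp_se = "Empirical standard error",
                rel_err_mod_se = "Relative error in model-based SE (%)",
                coverage = "Coverage of CI (%)")
  methods <- unique(perf$method)
  lines <- character(0)
  for (ms in names(measures)) {
    sub <- perf[perf$measure == ms, ]
    if (nrow(sub) == 0) next
    max_mcse <- suppressWarnings(max(sub$mcse, na.rm = TRUE))
    lines <- c(lines, sprintf("%s (max Monte Carlo error %.3g)",
                              measures[[ms]], max_mcse))
    hdr <- sprintf("  %-8s %s", "dgm",
                   paste(sprintf("%12s", methods), collapse = ""))
    lines <- c(lines, hdr)
    for (dg in unique(sub$dgm)) {
      vals <- vapply(methods, function(mm) {
        v <- sub$estimate[sub$dgm == dg & sub$method == mm]
        if (length(v) == 0 || is.na(v)) "." else
          formatC(v, format = "f",
                  digits = if (ms %in% c("coverage", "rel_err_mod_se")) 0
                           else digits)
      }, character(1))
      lines <- c(lines, sprintf("  %-8s %s", dg,
                                paste(sprintf("%12s", vals), collapse = "")))
    }
  }
  lines
}

#' @export
print.performance_table <- function(x, ...) {
  cat(format_performance(x), sep = "\n")
  cat("\n(per-cell estimates and Monte Carlo SEs in the underlying tibble;",
      "print with as_tibble())\n")
  invisible(x)
}
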