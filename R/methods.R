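# Analysis methods of the study: full-data logistic regression,
# complete-case analysis, multiple imputation with Rubin's rules, plus
# guarded execution and the hybrid-with-backup wrapper.

analysis_outcome <- function(rep_id, dgm, method, status = "ok",
                             estimate = NA_real_, se = NA_real_,
                             ci_low = NA_real_, ci_high = NA_real_,
                             separation = FALSE, backup_used = FALSE) {
  tibble::tibble(
    rep_id = as.integer(rep_id), dgm = dgm, method = method, status = status,
    estimate = estimate, se = se, ci_low = ci_low, ci_high = ci_high,
    separation = separation, backup_used = backup_used
  )
}

failed_outcome <- function(rep_id, dgm, method, code,
                           separation = FALSE, backup_used = FALSE) {
  analysis_outcome(rep_id, dgm, method, status = paste0("failed:", code),
                   separation = separation, backup_used = backup_used)
}

data_labels <- function(data) {
  list(rep_id = data$rep_id[1], dgm = data$dgm[1])
}

#' Analyse the full data or the complete cases
#'
#' Fits the analysis model (logistic regression of `D` on `E` and `C`) to
#' either every row using the true `C` (`subset = "all"`: the "full data"
#' benchmark, available only inside a simulation) or to the rows with `C`
#' observed (`subset = "complete_cases"`). The reported estimate is the `E`
#' coefficient -- the conditional log odds ratio -- with a Wald confidence
#' interval. Separation or a failed fit yields a `failed:` status, never an
#' error.
#'
#' @param data A simulated data set (columns `rep_id`, `dgm`, `C`, `E`,
#'   `D`, `M_C`).
#' @param subset `"all"` or `"complete_cases"`.
#' @param level Confidence level (default 0.95).
#' @param method_label Label stored in the outcome row; defaults to
#'   `"full"` or `"cca"` according to `subset`.
#' @param engine `"ml"` (default) or `"firth"`.
#' @param sep_threshold Divergence threshold passed to
#'   [detect_separation()] (ignored for the Firth engine, which is finite
#'   by construction).
#' @return A one-row analysis-outcome tibble: `rep_id`, `dgm`, `method`,
#'   `status`, `estimate`, `se`, `ci_low`, `ci_high`, `separation`,
#'   `backup_used`.
#' @export
analyze_complete_records <- function(data,
                                     subset = c("all", "complete_cases"),
                                     level = 0.95, method_label = NULL,
                                     engine = c("ml", "firth"),
                                     sep_threshold = 10) {
  subset <- match.arg(subset)
  engine <- match.arg(engine)
  if (is.null(method_label)) {
    method_label <- if (subset == "all") "full" else "cca"
  }
  lb <- data_labels(data)
  rows <- if (subset == "all") data else data[data$M_C == 0L, , drop = FALSE]
  if (nrow(rows) < 4L) {
    return(failed_outcome(lb$rep_id, lb$dgm, method_label, "too_few_rows"))
  }
  fit <- if (engine == "firth") fit_logistic_firth(rows)
         else fit_logistic_ml(rows)
  sep <- detect_separation(rows, fit = if (engine == "ml") fit,
                           threshold = sep_threshold)
  if (engine == "ml" && sep$separated) {
    return(failed_outcome(lb$rep_id, lb$dgm, method_label, sep$reason,
                          separation = TRUE))
  }
  if (!fit$converged || !is.finite(fit$coef[["E"]]) ||
      !is.finite(fit$se[["E"]])) {
    return(failed_outcome(lb$rep_id, lb$dgm, method_label, "nonconvergence",
                          separation = sep$separated))
  }
  z <- qnorm(1 - (1 - level) / 2)
  est <- fit$coef[["E"]]
  se <- fit$se[["E"]]
  analysis_outcome(lb$rep_id, lb$dgm, method_label,
                   estimate = est, se = se,
                   ci_low = est - z * se, ci_high = est + z * se,
                   separation = sep$separated)
}

#' Draw one proper imputation of the missing confounder
#'
#' Proper Normal-linear imputation of `C` given `E` and `D`: among the
#' observed-`C` rows, regress `C` on an intercept, `E` and `D`; draw the
#' residual variance from its scaled inverse-chi-squared posterior, draw
#' the coefficient vector from its Normal posterior given that variance,
#' and fill each missing `C` with its linear predictor plus fresh Normal
#' noise. The analysis outcome `D` is deliberately in the imputation model:
#' omitting it would bias the analysis towards the null.
#'
#' @param data A simulated data set.
#' @return The completed numeric `C` vector (equal to the input `C` where
#'   `M_C = 0`, and exactly the input where nothing is missing).
#' @export
impute_confounder_once <- function(data) {
  miss <- data$M_C == 1L
  if (!any(miss)) return(data$C)
  obs <- !miss
  n_obs <- sum(obs)
  p <- 3L
  if (n_obs < p + 2L) stop("too few complete rows to fit the imputation model",
                           call. = FALSE)
  X <- cbind(1, data$E, data$D)
  Xo <- X[obs, , drop = FALSE]
  qrX <- qr(Xo)
  if (qrX$rank < p) stop("singular imputation design (X'X not invertible)",
                         call. = FALSE)
  bhat <- qr.coef(qrX, data$C[obs])
  res <- qr.resid(qrX, data$C[obs])
  rss <- sum(res^2)
  xtx_inv <- chol2inv(qr.R(qrX))
  sigma2 <- rss / rchisq(1L, df = n_obs - p)
  bstar <- bhat + drop(crossprod(chol(sigma2 * xtx_inv), rnorm(p)))
  C_imp <- data$C
  C_imp[miss] <- drop(X[miss, , drop = FALSE] %*% bstar) +
    sqrt(sigma2) * rnorm(sum(miss))
  C_imp
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Combines `m` completed-data estimates and their variances: the pooled
#' point estimate is the mean `qbar`; the total variance is
#' `T = W + (1 + 1/m) B`, with `W` the mean within-imputation variance and
#' `B` the between-imputation sample variance. Interval degrees of freedom
#' follow Barnard and Rubin's small-sample formula with complete-data
#' degrees of freedom `df_com`.
#'
#' @param estimates Numeric vector of the `m` completed-data estimates
#'   (`m >= 2`).
#' @param variances Their squared standard errors (non-negative).
#' @param df_com Complete-data degrees of freedom (rows used minus number
#'   of model parameters); `Inf` allowed.
#' @return An object of class `pooled`: `qbar`, `W`, `B`, `T`, `df_BR`,
#'   `m`.
#' @examples
#' pool_rubin(c(1, 1.2, 0.8), c(0.25, 0.25, 0.25), df_com = 97)
#' @export
pool_rubin <- function(estimates, variances, df_com = Inf) {
  m <- length(estimates)
  if (m < 2L) stop("at least 2 imputations are needed to estimate the ",
                   "between-imputation variance", call. = FALSE)
  if (length(variances) != m) stop("`estimates` and `variances` lengths differ",
                                   call. = FALSE)
  if (any(variances < 0)) stop("`variances` must be non-negative", call. = FALSE)
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- var(estimates)
  Tv <- W + (1 + 1 / m) * B
  lambda <- if (Tv > 0) (1 + 1 / m) * B / Tv else 0
  df_old <- if (lambda > 0) (m - 1) / lambda^2 else Inf
  df_obs <- if (is.finite(df_com)) {
    (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
  } else {
    Inf
  }
  df_BR <- if (is.infinite(df_old) && is.infinite(df_obs)) Inf
           else 1 / (1 / df_old + 1 / df_obs)
  structure(list(qbar = qbar, W = W, B = B, T = Tv, df_BR = df_BR, m = m),
            class = "pooled")
}

#' @export
print.pooled <- function(x, ...) {
  cat(sprintf(
    "<pooled> m = %d: qbar = %.4f, W = %.4f, B = %.4f, T = %.4f, df = %.1f\n",
    x$m, x$qbar, x$W, x$B, x$T, x$df_BR))
  invisible(x)
}

#' Analyse by multiple imputation
#'
#' Imputes the missing confounder `m` times with
#' [impute_confounder_once()], fits the analysis model to each completed
#' data set, and pools with [pool_rubin()]. The confidence interval uses
#' the t distribution with Barnard-Rubin degrees of freedom. Failure of
#' any imputation or completed-data fit yields a `failed:` status.
#'
#' @param data A simulated data set.
#' @param m Number of imputations (default 20).
#' @param level Confidence level (default 0.95).
#' @param method_label Label stored in the outcome row (default `"mi"`).
#' @return A one-row analysis-outcome tibble (see
#'   [analyze_complete_records()]).
#' @export
analyze_mi <- function(data, m = 20L, level = 0.95, method_label = "mi") {
  stopifnot(m >= 2L)
  lb <- data_labels(data)
  ests <- vars <- numeric(m)
  for (i in seq_len(m)) {
    C_imp <- tryCatch(impute_confounder_once(data), error = function(e) NULL)
    if (is.null(C_imp)) {
      return(failed_outcome(lb$rep_id, lb$dgm, method_label, "impute_error"))
    }
    completed <- data
    completed$C <- C_imp
    fit <- fit_logistic_ml(completed)
    if (!fit$converged || !is.finite(fit$coef[["E"]]) ||
        !is.finite(fit$se[["E"]])) {
      return(failed_outcome(lb$rep_id, lb$dgm, method_label, "fit_error"))
    }
    ests[i] <- fit$coef[["E"]]
    vars[i] <- fit$se[["E"]]^2
  }
  pooled <- pool_rubin(ests, vars, df_com = nrow(data) - 3L)
  se <- sqrt(pooled$T)
  tq <- if (is.finite(pooled$df_BR)) {
    qt(1 - (1 - level) / 2, df = pooled$df_BR)
  } else {
    qnorm(1 - (1 - level) / 2)
  }
  analysis_outcome(lb$rep_id, lb$dgm, method_label,
                   estimate = pooled$qbar, se = se,
                   ci_low = pooled$qbar - tq * se,
                   ci_high = pooled$qbar + tq * se)
}

#' Run an analysis method, capturing any failure
#'
#' Wraps a method so that any condition raised inside it becomes a
#' `failed:<code>` outcome row instead of halting the simulation; this
#' guarantees one outcome row per repetition whatever the method does to
#' the data it is given.
#'
#' @param method A function taking the data set (and `...`) and returning
#'   a one-row analysis-outcome tibble.
#' @param data The simulated data set.
#' @param method_label Label used if the method dies before it can label
#'   its own outcome.
#' @param ... Passed on to `method`.
#' @return A one-row analysis-outcome tibble, always.
#' @export
run_method_guarded <- function(method, data, method_label = "unknown", ...) {
  tryCatch(
    method(data, ...),
    error = function(e) {
      code <- gsub("[^a-zA-Z0-9_ .-]", "", conditionMessage(e))
      code <- gsub("\\s+", "_", trimws(substr(code, 1L, 60L)))
      if (!nzchar(code)) code <- "error"
      lb <- data_labels(data)
      failed_outcome(lb$rep_id, lb$dgm, method_label, code)
    }
  )
}

default_trigger_rules <- function() {
  list(separation = TRUE, max_abs_estimate = 10, max_se = 100)
}

trigger_fires <- function(outcome, rules) {
  if (startsWith(outcome$status, "failed")) return(TRUE)
  if (isTRUE(rules$separation) && isTRUE(outcome$separation)) return(TRUE)
  if (!is.null(rules$max_abs_estimate) && is.finite(outcome$estimate) &&
      abs(outcome$estimate) > rules$max_abs_estimate) return(TRUE)
  if (!is.null(rules$max_se) && is.finite(outcome$se) &&
      outcome$se > rules$max_se) return(TRUE)
  FALSE
}

#' Run a primary method with an automatic backup procedure
#'
#' Runs the primary method under [run_method_guarded()]; if it fails or
#' returns an absurd result (separation flagged, estimate or standard
#' error beyond the trigger thresholds), runs the backup method instead
#' and flags `backup_used`. What the simulation then evaluates is the
#' hybrid procedure -- primary-with-backup -- which is usually closer to
#' what an analyst would actually do than the pure method; the count of
#' backup invocations is itself a performance measure worth reporting.
#'
#' @param primary,backup Method functions as in [run_method_guarded()].
#' @param data The simulated data set.
#' @param trigger Named list of trigger rules: `separation` (logical),
#'   `max_abs_estimate`, `max_se`. Defaults: separation, |estimate| > 10,
#'   se > 100.
#' @param method_label Label stored on the returned row (default
#'   `"cca_firth_hybrid"`).
#' @param ... Passed to both methods.
#' @return A one-row analysis-outcome tibble; `backup_used = TRUE` when
#'   the backup supplied the result. If the backup also fails the status
#'   is `failed:`.
#' @export
hybrid_with_backup <- function(primary, backup, data,
                               trigger = default_trigger_rules(),
                               method_label = "cca_firth_hybrid", ...) {
  out <- run_method_guarded(primary, data, method_label = method_label, ...)
  out$method <- method_label
  if (!trigger_fires(out, trigger)) {
    return(out)
  }
  sep_primary <- isTRUE(out$separation)
  out2 <- run_method_guarded(backup, data, method_label = method_label, ...)
  out2$method <- method_label
  out2$backup_used <- TRUE
  out2$separation <- out2$separation | sep_primary
  out2
}
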