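#' Specify a data-generating mechanism
#'
#' Defines one data-generating mechanism (DGM) for the missing-confounder
#' simulation: a standard-Normal confounder `C`, a binary exposure `E` drawn
#' from a logistic model on `C`, a binary outcome `D` drawn from a logistic
#' model on `E` and `C`, and a logistic missingness model for `C`. The true
#' estimand is the conditional E--D log odds ratio `betaE`; by default it is
#' zero, so any E--D association in the generated data is pure confounding
#' through `C`.
#'
#' The missingness mechanism constrains which coefficients may be non-zero:
#' MCAR (missing completely at random) allows only the intercept `gamma0`;
#' MAR (missing at random) additionally allows dependence on the observed
#' `E` and `D`; MNAR (missing not at random) allows dependence on the
#' possibly-unobserved `C` itself.
#'
#' @param label Identifier string for the mechanism (used as the `dgm`
#'   column in all output tables).
#' @param mechanism One of `"MCAR"`, `"MAR"`, `"MNAR"`.
#' @param n_obs Individuals per simulated data set (default 500).
#' @param alpha0,alphaC Intercept and `C` slope of the exposure model,
#'   on the logit scale: `E ~ Bernoulli(plogis(alpha0 + alphaC * C))`.
#' @param beta0,betaE,betaC Intercept, exposure and confounder coefficients
#'   of the outcome model: `D ~ Bernoulli(plogis(beta0 + betaE*E + betaC*C))`.
#'   `betaE` is the true estimand.
#' @param gamma0,gammaE,gammaD,gammaC Missingness-model coefficients:
#'   `M_C ~ Bernoulli(plogis(gamma0 + gammaE*E + gammaD*D + gammaC*C))`.
#' @return An object of class `dgm_spec`.
#' @examples
#' spec <- dgm_spec("mcar", "MCAR", gamma0 = qlogis(0.3))
#' head(generate_full(spec))
#' @export
dgm_spec <- function(label,
                     mechanism = c("MCAR", "MAR", "MNAR"),
                     n_obs = 500,
                     alpha0 = -1, alphaC = 1,
                     beta0 = -1, betaE = 0, betaC = 1,
                     gamma0 = qlogis(0.3),
                     gammaE = 0, gammaD = 0, gammaC = 0) {
  mechanism <- match.arg(mechanism)
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (n_obs < 1) stop("`n_obs` must be at least 1", call. = FALSE)
  if (mechanism == "MCAR" && !(gammaE == 0 && gammaD == 0 && gammaC == 0)) {
    stop("MCAR requires gammaE = gammaD = gammaC = 0", call. = FALSE)
  }
  if (mechanism == "MAR" && gammaC != 0) {
    stop("MAR requires gammaC = 0 (missingness may not depend on C)",
         call. = FALSE)
  }
  structure(
    list(label = label, mechanism = mechanism, n_obs = as.integer(n_obs),
         alpha0 = alpha0, alphaC = alphaC,
         beta0 = beta0, betaE = betaE, betaC = betaC,
         gamma0 = gamma0, gammaE = gammaE, gammaD = gammaD, gammaC = gammaC),
    class = "dgm_spec"
  )
}

#' @export
print.dgm_spec <- function(x, ...) {
  cat("<dgm_spec> ", x$label, " (", x$mechanism, "), n_obs = ", x$n_obs, "\n",
      sep = "")
  cat("  exposure:   logit P(E=1) = ", x$alpha0, " + ", x$alphaC, "*C\n",
      sep = "")
  cat("  outcome:    logit P(D=1) = ", x$beta0, " + ", x$betaE, "*E + ",
      x$betaC, "*C\n", sep = "")
  cat("  missing C:  logit P(M_C=1) = ", signif(x$gamma0, 4), " + ",
      x$gammaE, "*E + ", x$gammaD, "*D + ", x$gammaC, "*C\n", sep = "")
  invisible(x)
}

#' Default study mechanisms: MCAR, MAR and MNAR
#'
#' The three mechanisms of the packaged study, differing only in the
#' missingness model for `C`. All share exposure and outcome prevalences of
#' roughly 30% (keeping sparse-data analysis failures rare at n = 500) and
#' overall missingness of roughly 30%.
#'
#' @param n_obs Individuals per data set (default 500).
#' @return A named list of three [dgm_spec()] objects (`mcar`, `mar`, `mnar`).
#' @export
default_dgms <- function(n_obs = 500) {
  list(
    mcar = dgm_spec("mcar", "MCAR", n_obs = n_obs, gamma0 = qlogis(0.3)),
    mar  = dgm_spec("mar", "MAR", n_obs = n_obs,
                    gamma0 = -1.5, gammaE = 1, gammaD = 1),
    mnar = dgm_spec("mnar", "MNAR", n_obs = n_obs,
                    gamma0 = -1, gammaC = 1)
  )
}

#' Generate one full (pre-deletion) simulated data set
#'
#' Draws `C` i.i.d. standard Normal, then `E` and `D` from the spec's
#' logistic models, consuming the current random stream in the fixed order
#' C, then E, then D. The missingness indicator `M_C` is all zero: apply
#' [apply_missingness()] to impose the mechanism.
#'
#' @param spec A [dgm_spec()].
#' @param rep_id Repetition index recorded in the output (default 1).
#' @return A tibble with columns `rep_id`, `dgm`, `C`, `E`, `D`, `M_C`.
#' @export
generate_full <- function(spec, rep_id = 1L) {
  stopifnot(inherits(spec, "dgm_spec"))
  n <- spec$n_obs
  C <- rnorm(n)
  E <- rbinom(n, 1L, plogis(spec$alpha0 + spec$alphaC * C))
  D <- rbinom(n, 1L, plogis(spec$beta0 + spec$betaE * E + spec$betaC * C))
  tibble::tibble(rep_id = as.integer(rep_id), dgm = spec$label,
                 C = C, E = as.integer(E), D = as.integer(D), M_C = 0L)
}

#' Impose the missingness mechanism on a full data set
#'
#' Rewrites `M_C` as Bernoulli draws from the spec's missingness model.
#' `C` itself is retained even where `M_C = 1` (analyses mask it); this
#' keeps oracle comparisons against the full data possible.
#'
#' @param full A data set from [generate_full()] with `M_C` all zero.
#' @param spec The [dgm_spec()] supplying the missingness coefficients.
#' @return The data set with `M_C` redrawn; `C`, `E`, `D` unchanged.
#' @export
apply_missingness <- function(full, spec) {
  stopifnot(inherits(spec, "dgm_spec"))
  if (any(full$M_C != 0L)) {
    stop("`full` must have M_C all zero (a full, pre-deletion data set)",
         call. = FALSE)
  }
  pr <- plogis(spec$gamma0 + spec$gammaE * full$E +
                 spec$gammaD * full$D + spec$gammaC * full$C)
  full$M_C <- rbinom(nrow(full), 1L, pr)
  full
}

#' Mask missing confounder values
#'
#' Returns the analysis view of a simulated data set: `C` is `NA` wherever
#' `M_C = 1`.
#'
#' @param data A simulated data set.
#' @return The same tibble with masked `C`.
#' @export
mask_missing <- function(data) {
  data$C[data$M_C == 1L] <- NA_real_
  data
}

#' Large-sample self-check of a data-generating mechanism
#'
#' Generates a single very large data set and checks it against intentions:
#' the unconditional D--E cross-tabulation and its log odds ratio (under
#' confounding this is non-zero even though E does not cause D), refits of
#' the two generating logistic models with truth-in-CI verdicts per
#' coefficient, and the realized missingness fraction. A degenerate
#' cross-tabulation (a zero margin) is reported as a check failure rather
#' than raised as an error.
#'
#' @param spec A [dgm_spec()].
#' @param N Size of the single check data set (default 100000; must be at
#'   least 1000).
#' @param level Confidence level for the recovery intervals (default 0.95).
#' @return An object of class `dgm_check`: a list with the D--E table and
#'   log odds ratio, a tibble `coefficients` (model, term, truth, estimate,
#'   se, ci_low, ci_high, covers), the missingness fraction, and an overall
#'   `ok` flag (all CIs cover and the table is non-degenerate).
#' @export
large_sample_check <- function(spec, N = 100000, level = 0.95) {
  stopifnot(inherits(spec, "dgm_spec"))
  if (N < 1000) stop("`N` must be at least 1000", call. = FALSE)
  big_spec <- spec
  big_spec$n_obs <- as.integer(N)
  dat <- apply_missingness(generate_full(big_spec), big_spec)

  tab <- table(factor(dat$D, levels = 0:1), factor(dat$E, levels = 0:1))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  log_or <- if (degenerate || any(tab == 0)) NA_real_ else
    log(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]))

  z <- qnorm(1 - (1 - level) / 2)
  row_for <- function(model, fit, truth) {
    tibble::tibble(
      model = model, term = names(fit$coef), truth = truth,
      estimate = unname(fit$coef), se = unname(fit$se),
      ci_low = unname(fit$coef - z * fit$se),
      ci_high = unname(fit$coef + z * fit$se)
    )
  }
  fit_e <- fit_logistic_ml(dat, outcome = "E", predictors = "C")
  fit_d <- fit_logistic_ml(dat, outcome = "D", predictors = c("E", "C"))
  coefs <- dplyr::bind_rows(
    row_for("exposure", fit_e, c(spec$alpha0, spec$alphaC)),
    row_for("outcome", fit_d, c(spec$beta0, spec$betaE, spec$betaC))
  )
  coefs$covers <- coefs$ci_low <= coefs$truth & coefs$truth <= coefs$ci_high

  structure(
    list(label = spec$label, N = as.integer(N), table = tab,
         log_or_unconditional = log_or, degenerate = degenerate,
         coefficients = coefs, miss_frac = mean(dat$M_C),
         ok = !degenerate && !anyNA(coefs$covers) && all(coefs$covers)),
    class = "dgm_check"
  )
}

#' @export
print.dgm_check <- function(x, ...) {
  cat("<dgm_check> ", x$label, ", N = ", x$N, "\n", sep = "")
  cat("D x E cross-tabulation:\n")
  print(x$table)
  cat("unconditional D-E log OR:",
      if (is.na(x$log_or_unconditional)) "undefined (degenerate table)"
      else sprintf("%.3f", x$log_or_unconditional), "\n")
  cat(sprintf("missingness fraction: %.3f\n", x$miss_frac))
  print(x$coefficients, n = Inf)
  cat(if (isTRUE(x$ok)) "all recovery checks passed\n"
      else "RECOVERY CHECK FAILED\n")
  invisible(x)
}
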