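# Logistic model fitting: maximum likelihood (IRLS via stats::glm.fit) and
# Firth's Jeffreys-penalized variant, which stays finite under separation.

new_logit_fit <- function(coef, se, vcov, df, converged, n_used, iterations,
                          engine) {
  structure(
    list(coef = coef, se = se, vcov = vcov, df = df, converged = converged,
         n_used = as.integer(n_used), iterations = as.integer(iterations),
         engine = engine),
    class = "logit_fit"
  )
}

design_matrix <- function(data, outcome, predictors) {
  X <- cbind(`(Intercept)` = rep(1, nrow(data)))
  for (p in predictors) X <- cbind(X, as.numeric(data[[p]]))
  colnames(X) <- c("(Intercept)", predictors)
  list(X = X, y = as.numeric(data[[outcome]]))
}

#' Fit a logistic regression by maximum likelihood
#'
#' Iteratively reweighted least squares with standard errors from the
#' inverse observed information. Non-convergence and a singular information
#' matrix are reported through the `converged` flag -- never as an error --
#' so that a simulation loop is not halted by one unlucky data set.
#'
#' @param data Data frame holding the outcome and predictor columns.
#' @param outcome Name of the binary outcome column (default `"D"`).
#' @param predictors Predictor column names (default `c("E", "C")`); an
#'   intercept is always included.
#' @param maxit,tol Iteration cap and convergence tolerance.
#' @return A `logit_fit` object: named `coef` and `se` vectors (log-odds
#'   scale), `vcov`, `df` (`Inf`; Wald inference), `converged`, `n_used`,
#'   `iterations`.
#' @export
fit_logistic_ml <- function(data, outcome = "D", predictors = c("E", "C"),
                            maxit = 100L, tol = 1e-8) {
  d <- design_matrix(data, outcome, predictors)
  p <- ncol(d$X)
  nms <- colnames(d$X)
  failed <- function(iter = 0L) {
    new_logit_fit(setNames(rep(NA_real_, p), nms),
                  setNames(rep(NA_real_, p), nms),
                  matrix(NA_real_, p, p), Inf, FALSE, nrow(data), iter, "ml")
  }
  if (nrow(data) < p + 1L) return(failed())
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(
      d$X, d$y, family = stats::binomial(),
      control = stats::glm.control(epsilon = tol, maxit = maxit)
    )),
    error = function(e) NULL
  )
  if (is.null(fit) || fit$rank < p) return(failed())
  R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  R[lower.tri(R)] <- 0
  vc <- tryCatch(chol2inv(R), error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(vc))) return(failed(fit$iter))
  # undo the column pivoting applied inside glm.fit
  piv <- fit$qr$pivot
  vc[piv, piv] <- vc
  dimnames(vc) <- list(nms, nms)
  cf <- setNames(fit$coefficients[nms], nms)
  new_logit_fit(cf, sqrt(diag(vc)), vc, Inf,
                isTRUE(fit$converged), nrow(data), fit$iter, "ml")
}

#' Fit a Firth penalized logistic regression
#'
#' Maximizes the Jeffreys-penalized log-likelihood
#' `l(beta) + 0.5 * log det I(beta)` by a modified-score Newton iteration.
#' Unlike maximum likelihood, the penalized estimate is finite even under
#' separation (perfect prediction), which makes this the natural backup
#' analysis when a sparse data set defeats the primary fit.
#'
#' @inheritParams fit_logistic_ml
#' @return A `logit_fit` object (standard errors from the inverse Fisher
#'   information at the penalized estimate).
#' @export
fit_logistic_firth <- function(data, outcome = "D", predictors = c("E", "C"),
                               maxit = 100L, tol = 1e-8) {
  d <- design_matrix(data, outcome, predictors)
  X <- d$X
  y <- d$y
  p <- ncol(X)
  nms <- colnames(X)
  beta <- rep(0, p)
  converged <- FALSE
  iter <- 0L
  info <- NULL
  while (iter < maxit) {
    iter <- iter + 1L
    mu <- plogis(drop(X %*% beta))
    w <- mu * (1 - mu)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    ch <- tryCatch(chol(info), error = function(e) NULL)
    if (is.null(ch)) break
    inv <- chol2inv(ch)
    h <- rowSums((XW %*% inv) * XW)           # hat values
    score <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    delta <- drop(inv %*% score)
    if (max(abs(delta)) > 5) delta <- delta * 5 / max(abs(delta))
    beta <- beta + delta
    if (max(abs(delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (is.null(info)) {
    vc <- matrix(NA_real_, p, p, dimnames = list(nms, nms))
  } else {
    vc <- chol2inv(chol(info))
    dimnames(vc) <- list(nms, nms)
  }
  new_logit_fit(setNames(beta, nms), sqrt(diag(vc)), vc, Inf, converged,
                nrow(data), iter, "firth")
}

#' Detect separation (perfect prediction) in an exposure-outcome table
#'
#' Flags the data configurations under which logistic maximum likelihood
#' drifts to infinity: a zero margin of the E-by-D table restricted to the
#' analysis rows (no events, no non-events, no exposed, no unexposed), or
#' an already-fitted coefficient beyond a divergence threshold. Different
#' software reacts differently to these data sets -- dropping the exposure
#' and reporting zeros, or reporting huge estimates with huge standard
#' errors -- so the flag, not the fit, is the reliable signal.
#'
#' @param data Analysis rows with `E` and `D` columns.
#' @param fit Optional `logit_fit` on those rows; its largest absolute
#'   coefficient is compared against `threshold`.
#' @param threshold Divergence threshold on |coefficient| (default 10;
#'   pathological separated fits typically land beyond +/-10).
#' @return A list with `separated` (logical) and `reason` (one of
#'   `"no_events"`, `"no_nonevents"`, `"no_exposed"`, `"no_unexposed"`,
#'   `"divergent_fit"`, or `NA` when not separated).
#' @export
detect_separation <- function(data, fit = NULL, threshold = 10) {
  reason <- NA_character_
  if (all(data$D == 0)) reason <- "no_events"
  else if (all(data$D == 1)) reason <- "no_nonevents"
  else if (all(data$E == 0)) reason <- "no_exposed"
  else if (all(data$E == 1)) reason <- "no_unexposed"
  else if (!is.null(fit) && any(is.finite(fit$coef)) &&
           max(abs(fit$coef), na.rm = TRUE) > threshold) {
    reason <- "divergent_fit"
  }
  list(separated = !is.na(reason), reason = reason)
}

#' @export
print.logit_fit <- function(x, ...) {
  cat("<logit_fit> engine =", x$engine,
      "| converged =", x$converged,
      "| n =", x$n_used, "| iterations =", x$iterations, "\n")
  print(tibble::tibble(term = names(x$coef), estimate = unname(x$coef),
                       std.error = unname(x$se)))
  invisible(x)
}

#' Tidy a logistic fit
#'
#' @param x A `logit_fit`.
#' @param conf.level Confidence level for Wald intervals.
#' @param ... Unused.
#' @return A tibble with one row per term: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @exportS3Method generics::tidy
tidy.logit_fit <- function(x, conf.level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf.level) / 2)
  stat <- unname(x$coef / x$se)
  tibble::tibble(
    term = names(x$coef),
    estimate = unname(x$coef),
    std.error = unname(x$se),
    statistic = stat,
    p.value = 2 * pnorm(-abs(stat)),
    conf.low = unname(x$coef - z * x$se),
    conf.high = unname(x$coef + z * x$se)
  )
}

#' Glance at a logistic fit
#'
#' @param x A `logit_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `engine`, `converged`, `n_used`, `iterations`.
#' @exportS3Method generics::glance
glance.logit_fit <- function(x, ...) {
  tibble::tibble(engine = x$engine, converged = x$converged,
                 n_used = x$n_used, iterations = x$iterations)
}
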