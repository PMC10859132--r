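# Checking instruments: SE-vs-estimate scatter data, outlier flagging,
# zip-plot data, Monte Carlo compatibility checks, known-answer checks.

#' Standard-error-versus-estimate scatter data
#'
#' The single most revealing picture of an estimates data set: per
#' dgm-method cell, every repetition's (estimate, se) pair. Clusters of
#' huge standard errors, or zero standard errors paired with zero
#' estimates, are fingerprints of separation handled differently by
#' different software. Failed repetitions are dropped (they have no
#' estimate to plot).
#'
#' @param estimates An estimates tibble or `sim_study`.
#' @return A tibble `dgm`, `method`, `rep_id`, `estimate`, `se`.
#' @export
scatter_data <- function(estimates) {
  if (inherits(estimates, "sim_study")) estimates <- estimates$estimates
  ok_rows(estimates)[, c("dgm", "method", "rep_id", "estimate", "se")]
}

#' Default outlier-flagging rules
#'
#' |estimate| > 10 (log odds ratios beyond that are not believable
#' analysis results), se > 100 (separated fits report standard errors in
#' the thousands), se < 1e-8 (software that drops a separated covariate
#' reports exact zeros).
#'
#' @return A named list `max_abs_estimate`, `max_se`, `min_se`.
#' @export
default_outlier_rules <- function() {
  list(max_abs_estimate = 10, max_se = 100, min_se = 1e-8)
}

#' Flag outlying repetitions
#'
#' Flags non-failed rows violating any rule; a handful of outliers rarely
#' moves coverage but can wreck bias and the model-based standard error,
#' so the flagged rows should be recreated and understood, not silently
#' dropped.
#'
#' @param estimates An estimates tibble or `sim_study`.
#' @param rules Named thresholds (`max_abs_estimate`, `max_se`, `min_se`);
#'   omit (set `NULL`) any rule to disable it. An empty list flags
#'   nothing.
#' @return An `outlier_report`: `flagged` tibble (`rep_id`, `dgm`,
#'   `method`, `estimate`, `se`, `rule`), the echoed `rules`, and `counts`
#'   per dgm-method cell.
#' @export
flag_outliers <- function(estimates, rules = default_outlier_rules()) {
  if (inherits(estimates, "sim_study")) estimates <- estimates$estimates
  okc <- ok_rows(estimates)
  hits <- list()
  if (!is.null(rules$max_abs_estimate)) {
    h <- okc[abs(okc$estimate) > rules$max_abs_estimate, ]
    if (nrow(h)) hits <- c(hits, list(dplyr::mutate(h, rule = "max_abs_estimate")))
  }
  if (!is.null(rules$max_se)) {
    h <- okc[okc$se > rules$max_se, ]
    if (nrow(h)) hits <- c(hits, list(dplyr::mutate(h, rule = "max_se")))
  }
  if (!is.null(rules$min_se)) {
    h <- okc[okc$se < rules$min_se, ]
    if (nrow(h)) hits <- c(hits, list(dplyr::mutate(h, rule = "min_se")))
  }
  flagged <- if (length(hits)) {
    dplyr::bind_rows(hits)[, c("rep_id", "dgm", "method", "estimate", "se",
                               "rule")]
  } else {
    tibble::tibble(rep_id = integer(), dgm = character(),
                   method = character(), estimate = double(), se = double(),
                   rule = character())
  }
  counts <- flagged |>
    dplyr::count(.data$dgm, .data$method, name = "n_flagged")
  structure(list(flagged = flagged, rules = rules, counts = counts),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("<outlier_report> rules:",
      paste(names(x$rules), unlist(x$rules), sep = "=", collapse = ", "), "\n")
  if (nrow(x$flagged) == 0L) {
    cat("no rows flagged\n")
  } else {
    cat(nrow(x$flagged), "row(s) flagged:\n")
    print(x$flagged, n = 20)
  }
  invisible(x)
}

#' Zip-plot data: intervals ranked by compatibility with the truth
#'
#' For each dgm-method cell, ranks the repetitions' confidence intervals
#' by their two-sided Wald p-value against the true value (least
#' compatible first, ties broken by repetition id) and records whether
#' each interval covers. Stacking the intervals in this order shows at a
#' glance whether poor coverage comes from bias (non-covering intervals
#' pile up on one side of the truth) or from too-narrow intervals
#' (non-coverers appear symmetrically).
#'
#' @param estimates An estimates tibble or `sim_study`.
#' @param theta True estimand value.
#' @return A tibble `dgm`, `method`, `rep_id`, `rank_fraction`
#'   (`(rank - 0.5)/n`), `p_value`, `ci_low`, `ci_high`, `covers`, with an
#'   attribute `n_zero_se` counting the excluded zero-SE rows (their
#'   p-value is undefined); a warning is issued when any are excluded.
#' @export
zip_plot_data <- function(estimates, theta = 0) {
  if (inherits(estimates, "sim_study")) estimates <- estimates$estimates
  okc <- ok_rows(estimates)
  zero_se <- okc$se <= 0
  n_zero <- sum(zero_se)
  if (n_zero > 0L) {
    warning(n_zero, " row(s) with zero standard error excluded from the ",
            "zip data (undefined p-value)", call. = FALSE)
  }
  okc <- okc[!zero_se, , drop = FALSE]
  if (nrow(okc) == 0L) stop("no usable rows for the zip plot", call. = FALSE)
  res <- okc |>
    dplyr::mutate(p_value = 2 * pnorm(-abs(.data$estimate - theta) / .data$se),
                  covers = .data$ci_low <= theta & theta <= .data$ci_high) |>
    dplyr::group_by(.data$dgm, .data$method) |>
    dplyr::arrange(.data$p_value, .data$rep_id, .by_group = TRUE) |>
    dplyr::mutate(rank_fraction = (dplyr::row_number() - 0.5) / dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::select("dgm", "method", "rep_id", "rank_fraction", "p_value",
                  "ci_low", "ci_high", "covers")
  attr(res, "n_zero_se") <- n_zero
  res
}

#' Is a result compatible with Monte Carlo error?
#'
#' Before concluding that a surprising performance estimate reveals a bug
#' (or a discovery), check it against its own Monte Carlo standard error:
#' the verdict is "compatible" when the estimate lies strictly within
#' 2 MCSE of the reference value. A 100-repetition run with bias MCSE
#' 0.049, say, cannot distinguish an observed bias of -0.094 from zero
#' (margin 0.098).
#'
#' @param estimate The performance-measure estimate.
#' @param mcse Its Monte Carlo standard error (> 0).
#' @param reference The value it is being compared against.
#' @return An `mc_verdict`: `compatible` (logical, strict inequality),
#'   `margin` (`2 * mcse`), `difference`.
#' @export
mc_compatibility_check <- function(estimate, mcse, reference = 0) {
  stopifnot(mcse > 0)
  diff <- estimate - reference
  structure(
    list(compatible = abs(diff) < 2 * mcse, margin = 2 * mcse,
         difference = diff, estimate = estimate, reference = reference),
    class = "mc_verdict"
  )
}

#' @export
print.mc_verdict <- function(x, ...) {
  cat(sprintf(
    "<mc_verdict> %s: |%.4g - %.4g| = %.4g vs margin 2*mcse = %.4g\n",
    if (x$compatible) "compatible" else "NOT compatible",
    x$estimate, x$reference, abs(x$difference), x$margin))
  invisible(x)
}

#' Known-answer checks on a performance table
#'
#' A simulation study should contain settings where the answer is known,
#' and this helper verifies the ones built into the packaged study:
#' (a) full-data bias compatible with 0; (b) full-data coverage compatible
#' with the nominal level; (c) under MCAR, complete-case bias compatible
#' with 0 and coverage compatible with nominal (deleting completely at
#' random costs precision, not validity); (d) empirical-SE ordering
#' full <= MI <= CCA under MCAR. Compatibility is the strict 2-MCSE
#' criterion of [mc_compatibility_check()]. Checks whose cells are absent
#' are reported as skipped, not failed.
#'
#' @param perf A [performance_table()].
#' @param dgm_mcar Label of the MCAR mechanism (default `"mcar"`).
#' @param method_full,method_cca,method_mi Method labels.
#' @param nominal Nominal coverage in percent (default 95).
#' @return A tibble `check`, `status` (`"pass"`, `"fail"`, `"skipped"`),
#'   `detail`.
#' @export
known_property_checks <- function(perf, dgm_mcar = "mcar",
                                  method_full = "full", method_cca = "cca",
                                  method_mi = "mi", nominal = 95) {
  get_cell <- function(dg, mm, ms) {
    row <- perf[perf$dgm == dg & perf$method == mm & perf$measure == ms, ]
    if (nrow(row) == 1L && is.finite(row$estimate)) row else NULL
  }
  dgms <- unique(perf$dgm)
  rows <- list()
  add <- function(check, status, detail) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      check = check, status = status, detail = detail)
  }
  compat <- function(cell, ref) mc_compatibility_check(cell$estimate,
                                                       cell$mcse, ref)
  check_compat <- function(name, cell, ref) {
    if (is.null(cell)) {
      add(name, "skipped", "required cell absent")
    } else {
      v <- compat(cell, ref)
      add(name, if (v$compatible) "pass" else "fail",
          sprintf("estimate %.4g vs %.4g, margin %.4g", cell$estimate, ref,
                  v$margin))
    }
  }
  for (dg in dgms) {
    check_compat(paste0("full-data bias = 0 [", dg, "]"),
                 get_cell(dg, method_full, "bias"), 0)
    check_compat(paste0("full-data coverage = nominal [", dg, "]"),
                 get_cell(dg, method_full, "coverage"), nominal)
  }
  check_compat("MCAR complete-case bias = 0",
               get_cell(dgm_mcar, method_cca, "bias"), 0)
  check_compat("MCAR complete-case coverage = nominal",
               get_cell(dgm_mcar, method_cca, "coverage"), nominal)
  e_full <- get_cell(dgm_mcar, method_full, "emp_se")
  e_cca <- get_cell(dgm_mcar, method_cca, "emp_se")
  e_mi <- get_cell(dgm_mcar, method_mi, "emp_se")
  if (is.null(e_full) || is.null(e_cca) || is.null(e_mi)) {
    add("MCAR empirical-SE ordering full <= MI <= CCA", "skipped",
        "required cell absent")
  } else {
    ok <- e_full$estimate <= e_mi$estimate && e_mi$estimate <= e_cca$estimate
    add("MCAR empirical-SE ordering full <= MI <= CCA",
        if (ok) "pass" else "fail",
        sprintf("full %.3f, MI %.3f, CCA %.3f", e_full$estimate,
                e_mi$estimate, e_cca$estimate))
  }
  dplyr::bind_rows(rows)
}
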