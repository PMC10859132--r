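# Diagnostics: scatter data, outlier flagging, zip plots, Monte Carlo
# compatibility, known-answer checks.

test_that("scatter data keeps one point per non-failed repetition per cell", {
  set.seed(601)
  est <- dplyr::bind_rows(
    random_estimates_cell(3, method = "m1"),
    random_estimates_cell(3, method = "m2")
  )
  sc <- scatter_data(est)
  expect_identical(nrow(sc), 6L)
  expect_identical(as.integer(table(sc$method)), c(3L, 3L))
  est$status[1] <- "failed:x"
  expect_identical(nrow(scatter_data(est)), 5L)
})

test_that("outlier rules flag the documented pathologies", {
  set.seed(602)
  clean <- random_estimates_cell(50)
  expect_identical(nrow(flag_outliers(clean)$flagged), 0L)

  bad <- clean
  bad$se[1] <- 3000                      # separated fit, huge claimed SE
  bad$estimate[2] <- -15                 # absurd log odds ratio
  bad$se[3] <- 0                         # dropped-covariate zero SE
  rep_out <- flag_outliers(bad)
  expect_setequal(rep_out$flagged$rule[rep_out$flagged$rep_id %in% 1:3],
                  c("max_se", "max_abs_estimate", "min_se"))
  expect_true(all(c("max_se") %in%
                    rep_out$flagged$rule[rep_out$flagged$rep_id == 1]))
})

test_that("empty rules flag nothing and tighter rules flag monotonically more", {
  set.seed(603)
  est <- random_estimates_cell(200)
  expect_identical(nrow(flag_outliers(est, rules = list())$flagged), 0L)
  loose <- flag_outliers(est, rules = list(max_abs_estimate = 1))$flagged
  tight <- flag_outliers(est, rules = list(max_abs_estimate = 0.5))$flagged
  expect_true(all(loose$rep_id %in% tight$rep_id))
  expect_gte(nrow(tight), nrow(loose))
})

test_that("a single interval gets rank fraction one half", {
  est <- random_estimates_cell(1)
  est$ci_low <- -1
  est$ci_high <- 1
  est$estimate <- 0.2
  est$se <- 0.5
  zip <- zip_plot_data(est, theta = 0)
  expect_identical(nrow(zip), 1L)
  expect_equal(zip$rank_fraction, 0.5)
  expect_true(zip$covers)
})

test_that("well-calibrated intervals zip correctly; biased ones pile up one-sided", {
  set.seed(604)
  n <- 1000
  make <- function(shift) {
    e <- rnorm(n) + shift
    tibble::tibble(rep_id = 1:n, dgm = "g", method = "m", status = "ok",
                   estimate = e, se = 1,
                   ci_low = e - qnorm(0.975), ci_high = e + qnorm(0.975),
                   separation = FALSE, backup_used = FALSE)
  }
  zip0 <- zip_plot_data(make(0), theta = 0)
  expect_equal(mean(zip0$covers), 0.95, tolerance = 0.02)
  # non-coverers are exactly the low-rank (least compatible) intervals
  expect_lt(max(zip0$rank_fraction[!zip0$covers]),
            min(zip0$rank_fraction[zip0$covers]))
  # non-coverage symmetric around the truth for the unbiased estimator
  miss0 <- zip0[!zip0$covers, ]
  expect_gt(min(mean(miss0$ci_high < 0), mean(miss0$ci_low > 0)), 0.2)

  zip_neg <- zip_plot_data(make(-1), theta = 0)
  miss <- zip_neg[!zip_neg$covers, ]
  expect_lt(mean(zip_neg$covers), 0.90)
  expect_gt(sum(miss$ci_high < 0), 5 * sum(miss$ci_low > 0))
})

test_that("zip non-coverage agrees with the coverage measure exactly", {
  set.seed(605)
  est <- random_estimates_cell(400)
  zip <- zip_plot_data(est, theta = 0)
  cov <- coverage(est$ci_low, est$ci_high, 0)$estimate
  expect_identical(sum(!zip$covers),
                   sum(!(est$ci_low <= 0 & 0 <= est$ci_high)))
  expect_equal(100 * mean(!zip$covers), 100 - cov)
})

test_that("the p-value ranking is equivariant to a common scale change", {
  set.seed(606)
  est <- random_estimates_cell(100)
  scaled <- est
  scaled$estimate <- est$estimate * 3
  scaled$se <- est$se * 3
  scaled$ci_low <- est$ci_low * 3
  scaled$ci_high <- est$ci_high * 3
  o1 <- zip_plot_data(est, theta = 0)
  o2 <- zip_plot_data(scaled, theta = 0)
  expect_identical(o1$rep_id, o2$rep_id)
  expect_equal(o1$p_value, o2$p_value)
})

test_that("zero-SE rows are excluded from zip data with a warning", {
  est <- random_estimates_cell(10)
  est$se[3] <- 0
  expect_warning(zip <- zip_plot_data(est, theta = 0), "zero standard error")
  expect_identical(nrow(zip), 9L)
  expect_identical(attr(zip, "n_zero_se"), 1L)
})

test_that("Monte Carlo compatibility uses a strict 2-mcse margin", {
  v <- mc_compatibility_check(-0.094, 0.049, 0)
  expect_true(v$compatible)
  expect_identical(v$margin, 0.098)
  expect_false(mc_compatibility_check(0.10, 0.01, 0)$compatible)
  # exactly at the boundary: not compatible (strict inequality)
  expect_false(mc_compatibility_check(0.02, 0.01, 0)$compatible)
})

test_that("known-answer checks pass, fail and skip as designed", {
  mk <- function(dgm, method, measure, estimate, mcse) {
    tibble::tibble(dgm = dgm, method = method, measure = measure,
                   estimate = estimate, mcse = mcse,
                   n_used = 100L, n_failed = 0L)
  }
  perf <- dplyr::bind_rows(
    mk("mcar", "full", "bias", 0.001, 0.01),
    mk("mcar", "full", "coverage", 95.4, 0.7),
    mk("mcar", "cca", "bias", -0.005, 0.012),
    mk("mcar", "cca", "coverage", 94.6, 0.8),
    mk("mcar", "full", "emp_se", 0.40, 0.01),
    mk("mcar", "mi", "emp_se", 0.45, 0.01),
    mk("mcar", "cca", "emp_se", 0.50, 0.01)
  )
  checks <- known_property_checks(perf)
  expect_true(all(checks$status %in% c("pass", "skipped")))
  expect_identical(
    checks$status[checks$check == "MCAR empirical-SE ordering full <= MI <= CCA"],
    "pass")

  bad <- perf
  bad$estimate[bad$method == "full" & bad$measure == "coverage"] <- 80
  bad$mcse[bad$method == "full" & bad$measure == "coverage"] <- 1
  checks_bad <- known_property_checks(bad)
  expect_identical(
    checks_bad$status[checks_bad$check == "full-data coverage = nominal [mcar]"],
    "fail")

  no_mi <- perf[perf$method != "mi", ]
  checks_skip <- known_property_checks(no_mi)
  expect_identical(
    checks_skip$status[checks_skip$check ==
                         "MCAR empirical-SE ordering full <= MI <= CCA"],
    "skipped")
})

test_that("plot layers build on the diagnostic data without error", {
  set.seed(607)
  est <- dplyr::bind_rows(random_estimates_cell(20, method = "m1"),
                          random_estimates_cell(20, method = "m2"))
  p1 <- plot_scatter(est)
  p2 <- plot_zip(est)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p1))
  expect_no_error(ggplot2::ggplot_build(p2))
})
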