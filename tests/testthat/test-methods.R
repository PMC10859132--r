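# Analysis methods: subset analyses, proper imputation, Rubin pooling,
# guarded execution and the hybrid backup.

make_data <- function(spec, seed) {
  set.seed(seed)
  apply_missingness(generate_full(spec), spec)
}

test_that("full-data and complete-case analyses coincide when nothing is missing", {
  spec <- dgm_spec("none", "MCAR", n_obs = 300, gamma0 = -30)
  dat <- make_data(spec, 301)
  a <- analyze_complete_records(dat, "all")
  b <- analyze_complete_records(dat, "complete_cases")
  expect_identical(a$estimate, b$estimate)
  expect_identical(a$se, b$se)
  expect_identical(a$status, "ok")
  expect_identical(a$method, "full")
  expect_identical(b$method, "cca")
})

test_that("complete cases with no events fail cleanly, never crash", {
  set.seed(302)
  dat <- tibble::tibble(
    rep_id = 1L, dgm = "x", C = rnorm(40),
    E = rbinom(40, 1L, 0.5), D = rep(0:1, each = 20),
    M_C = rep(c(0L, 1L), each = 20)   # every observed-C row has D = 0
  )
  out <- analyze_complete_records(dat, "complete_cases")
  expect_match(out$status, "^failed:no_events$")
  expect_true(out$separation)
  expect_true(is.na(out$estimate) && is.na(out$se) && is.na(out$ci_low))
})

test_that("imputation is the identity when nothing is missing", {
  spec <- dgm_spec("none", "MCAR", n_obs = 100, gamma0 = -30)
  dat <- make_data(spec, 303)
  expect_identical(impute_confounder_once(dat), dat$C)
})

test_that("successive imputations of the same data differ", {
  dat <- make_data(default_dgms()$mcar, 304)
  set.seed(305)
  a <- impute_confounder_once(dat)
  b <- impute_confounder_once(dat)
  expect_false(identical(a, b))
  expect_identical(a[dat$M_C == 0], b[dat$M_C == 0])
})

test_that("imputed C matches the observed conditional distribution under MCAR", {
  spec <- dgm_spec("big", "MCAR", n_obs = 100000, gamma0 = qlogis(0.3))
  dat <- make_data(spec, 306)
  imp <- impute_confounder_once(dat)
  for (e in 0:1) for (d in 0:1) {
    cell_obs <- dat$M_C == 0 & dat$E == e & dat$D == d
    cell_mis <- dat$M_C == 1 & dat$E == e & dat$D == d
    tol <- 4 * sd(dat$C[cell_obs]) *
      sqrt(1 / sum(cell_obs) + 1 / sum(cell_mis))
    expect_lt(abs(mean(imp[cell_mis]) - mean(dat$C[cell_obs])), tol)
  }
})

test_that("imputation fails informatively with too few complete rows", {
  dat <- tibble::tibble(rep_id = 1L, dgm = "x", C = rnorm(10),
                        E = rep(0:1, 5), D = rep(0:1, each = 5),
                        M_C = c(rep(1L, 7), 0L, 0L, 0L))
  expect_error(impute_confounder_once(dat), "complete rows")
})

test_that("Rubin pooling reproduces hand arithmetic", {
  p1 <- pool_rubin(c(1, 1), c(4, 4))
  expect_equal(p1$qbar, 1)
  expect_equal(p1$B, 0)
  expect_equal(p1$T, 4)

  p2 <- pool_rubin(c(1.0, 1.2, 0.8), c(0.25, 0.25, 0.25))
  expect_equal(p2$qbar, 1.0)
  expect_equal(p2$W, 0.25)
  expect_equal(p2$B, 0.04)
  expect_equal(p2$T, 0.25 + (4 / 3) * 0.04)

  expect_error(pool_rubin(1, 1), "at least 2")
  expect_error(pool_rubin(c(1, 2), c(1, -1)), "non-negative")
})

test_that("pooling is permutation invariant, scales with the variances, and T >= W", {
  set.seed(307)
  for (i in 1:200) {
    m <- sample(2:10, 1)
    est <- rnorm(m)
    v <- rchisq(m, 3)
    p <- pool_rubin(est, v, df_com = 50)
    expect_gte(p$T, p$W)
    perm <- sample(m)
    pp <- pool_rubin(est[perm], v[perm], df_com = 50)
    expect_equal(pp[c("qbar", "W", "B", "T", "df_BR")],
                 p[c("qbar", "W", "B", "T", "df_BR")])
  }
  p <- pool_rubin(c(0.5, 0.7, 0.3), c(1, 2, 3))
  ps <- pool_rubin(c(0.5, 0.7, 0.3), 10 * c(1, 2, 3))
  expect_equal(ps$W, 10 * p$W)
  expect_equal(ps$T - (1 + 1 / 3) * ps$B, 10 * (p$T - (1 + 1 / 3) * p$B))
})

test_that("MI with zero missingness equals the full-data point estimate", {
  spec <- dgm_spec("none", "MCAR", n_obs = 300, gamma0 = -30)
  dat <- make_data(spec, 308)
  full <- analyze_complete_records(dat, "all")
  mi <- analyze_mi(dat, m = 3)
  expect_equal(mi$estimate, full$estimate)
  expect_equal(mi$se, full$se)   # B = 0, so T = W = full-data variance
  expect_identical(mi$status, "ok")
})

test_that("guarded execution converts any raised condition to a failed row", {
  dat <- make_data(default_dgms()$mcar, 309)
  bomb <- function(d, ...) stop("imputation model exploded")
  out <- run_method_guarded(bomb, dat, method_label = "bomb")
  expect_match(out$status, "^failed:")
  expect_match(out$status, "exploded")
  expect_identical(out$method, "bomb")
  expect_identical(out$rep_id, dat$rep_id[1])
  expect_true(is.na(out$estimate))
})

test_that("a sparse mechanism produces captured failures and a complete run", {
  spec <- dgm_spec("sparse", "MCAR", n_obs = 50, alpha0 = -3, beta0 = -3,
                   gamma0 = qlogis(0.3))
  plan <- run_plan(spec, methods = "cca", n_sim = 100, seed = 310)
  run <- run_study(plan)
  expect_identical(nrow(run$estimates), 100L)
  n_failed <- sum(startsWith(run$estimates$status, "failed"))
  expect_gt(n_failed, 0)
  # and a healthy mechanism at the study defaults has none
  plan2 <- run_plan(default_dgms()$mcar, methods = c("full", "cca"),
                    n_sim = 50, seed = 311)
  run2 <- run_study(plan2)
  expect_identical(sum(startsWith(run2$estimates$status, "failed")), 0L)
})

test_that("the hybrid returns the primary result when nothing triggers", {
  dat <- make_data(default_dgms()$mcar, 312)
  out <- hybrid_with_backup(
    primary = function(d, ...) analyze_complete_records(
      d, "complete_cases", method_label = "cca_firth_hybrid"),
    backup = function(d, ...) analyze_complete_records(
      d, "complete_cases", method_label = "cca_firth_hybrid",
      engine = "firth"),
    data = dat
  )
  expect_identical(out$status, "ok")
  expect_false(out$backup_used)
})

test_that("the Firth backup rescues a separated complete-case analysis", {
  set.seed(313)
  dat <- tibble::tibble(
    rep_id = 1L, dgm = "x", C = rnorm(60),
    E = rbinom(60, 1L, 0.5), D = c(rep(0L, 30), rep(1L, 30)),
    M_C = c(rep(0L, 30), rep(1L, 30))   # observed-C rows: all D = 0
  )
  out <- hybrid_with_backup(
    primary = function(d, ...) analyze_complete_records(
      d, "complete_cases", method_label = "cca_firth_hybrid"),
    backup = function(d, ...) analyze_complete_records(
      d, "complete_cases", method_label = "cca_firth_hybrid",
      engine = "firth"),
    data = dat
  )
  expect_identical(out$status, "ok")
  expect_true(out$backup_used)
  expect_true(out$separation)
  expect_true(is.finite(out$estimate) && is.finite(out$se))
})

test_that("a huge standard error trips the backup trigger", {
  dat <- make_data(default_dgms()$mcar, 314)
  absurd <- function(d, ...) {
    out <- analyze_complete_records(d, "complete_cases",
                                    method_label = "cca_firth_hybrid")
    out$se <- 3000
    out
  }
  sane <- function(d, ...) analyze_complete_records(
    d, "complete_cases", method_label = "cca_firth_hybrid",
    engine = "firth")
  out <- hybrid_with_backup(absurd, sane, dat)
  expect_true(out$backup_used)
  expect_lt(out$se, 100)
  # if the backup also fails, the hybrid fails
  bomb <- function(d, ...) stop("backup dead")
  out2 <- hybrid_with_backup(absurd, bomb, dat)
  expect_match(out2$status, "^failed:")
})
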