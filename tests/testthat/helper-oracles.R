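# Independent oracles used across the suite. These evaluate objectives
# directly (grid refinement, one-pass loops) and share no code with the
# package's estimation or performance paths.

# iterative grid-refinement maximizer: evaluates `obj` on a full grid,
# zooms on the best point; resolution after `levels` rounds is
# (hi-lo) * (2/(points-1))^levels per coordinate
grid_maximize <- function(obj, lower, upper, levels = 7, points = 11) {
  p <- length(lower)
  lo <- lower
  hi <- upper
  best <- NULL
  for (lv in seq_len(levels)) {
    axes <- lapply(seq_len(p), function(j) seq(lo[j], hi[j], length.out = points))
    grid <- as.matrix(expand.grid(axes))
    vals <- apply(grid, 1, obj)
    best <- grid[which.max(vals), ]
    half <- (hi - lo) / (points - 1)
    lo <- best - half
    hi <- best + half
  }
  unname(best)
}

loglik_logit <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

loglik_firth <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- mu * (1 - mu)
  info <- crossprod(X * sqrt(w))
  ld <- determinant(info, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  loglik_logit(beta, X, y) + 0.5 * as.numeric(ld$modulus)
}

# a fixed 20-row (D, E, C) fixture for the fit oracles
fixture20 <- function() {
  data.frame(
    E = rep(0:1, 10),
    C = c(1.37, -0.56, 0.36, 0.63, 0.4, -0.11, 1.51, -0.09, 2.02, -0.06,
          1.3, 2.29, -1.39, -0.28, -0.13, 0.64, -0.28, -2.66, -2.44, 1.32),
    D = c(1, 0, 0, 0, 1, 0, 0, 0, 0, 0, 1, 1, 0, 1, 0, 0, 1, 0, 0, 1)
  )
}

# perfectly balanced null data: equal counts in all 8 (D, E, sign-of-C)
# cells; by symmetry every logistic coefficient is zero
balanced_null <- function(per_cell = 2) {
  g <- expand.grid(D = 0:1, E = 0:1, C = c(-1, 1))
  g[rep(seq_len(nrow(g)), each = per_cell), ]
}

# one-pass reference implementation of the performance measures,
# independent of the package's vectorised path
naive_performance <- function(est, se, lo, hi, theta) {
  n <- length(est)
  s <- 0
  for (e in est) s <- s + e
  mean_est <- s / n
  ss <- 0
  for (e in est) ss <- ss + (e - mean_est)^2
  sd_est <- sqrt(ss / (n - 1))
  bias_est <- mean_est - theta
  bias_mcse <- sd_est / sqrt(n)
  emp <- sd_est
  emp_mcse <- emp / sqrt(2 * (n - 1))
  ms <- 0
  for (v in se) ms <- ms + v^2
  mod <- sqrt(ms / n)
  vs <- 0
  for (v in se) vs <- vs + (v^2 - ms / n)^2
  var_se2 <- vs / (n - 1)
  mod_mcse <- sqrt(var_se2 / (4 * n * mod^2))
  rel <- 100 * (mod / emp - 1)
  rel_mcse <- 100 * (mod / emp) * sqrt(mod_mcse^2 / mod^2 + 1 / (2 * (n - 1)))
  cnt <- 0
  for (i in seq_len(n)) if (lo[i] <= theta && theta <= hi[i]) cnt <- cnt + 1
  p <- cnt / n
  cov_est <- 100 * p
  cov_mcse <- 100 * sqrt(p * (1 - p) / n)
  list(bias = c(bias_est, bias_mcse), emp_se = c(emp, emp_mcse),
       mod_se = c(mod, mod_mcse), rel_err_mod_se = c(rel, rel_mcse),
       coverage = c(cov_est, cov_mcse))
}

# random estimates-table fixture for one dgm x method cell
random_estimates_cell <- function(n, dgm = "g1", method = "m1") {
  est <- rnorm(n, 0, 0.5)
  se <- sqrt(rchisq(n, 5) / 5) * 0.4
  tibble::tibble(
    rep_id = seq_len(n), dgm = dgm, method = method, status = "ok",
    estimate = est, se = se,
    ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
    separation = FALSE, backup_used = FALSE
  )
}
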