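# The simulation engine: a single random stream drives everything, its
# state is captured (never re-set) at the start of each repetition, and any
# repetition's data set can be recreated exactly from the stored state.

STATE_TOKEN_FORMAT <- "r-serialize-b64-v1"

capture_state <- function() {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)   # force stream initialization
  }
  jsonlite::base64_enc(serialize(
    get(".Random.seed", envir = globalenv(), inherits = FALSE), NULL))
}

#' Restore a stored random-number state
#'
#' Writes a state token (as stored in a states data set) back into the
#' generator, so the draws that followed the capture can be replayed.
#'
#' @param token A base64 state token from [run_study()]'s states table.
#' @return Invisibly, the token.
#' @export
restore_state <- function(token) {
  state <- unserialize(jsonlite::base64_dec(token))
  assign(".Random.seed", state, envir = globalenv())
  invisible(token)
}

#' Plan a simulation run
#'
#' Collects the data-generating mechanisms, analysis methods and run
#' parameters of one simulation study. The seed is mandatory: a run is
#' fully determined by its plan, and re-running the same plan reproduces
#' every output byte for byte.
#'
#' @param dgm_specs A list of [dgm_spec()] objects (or a single one).
#' @param methods Character vector of method labels, each one of `"full"`
#'   (logistic regression on the pre-deletion data), `"cca"`
#'   (complete cases), `"mi"` (multiple imputation), `"cca_firth_hybrid"`
#'   (complete cases with a Firth backup).
#' @param n_sim Repetitions per mechanism (default 1000). Three are often
#'   enough for a first smoke run.
#' @param seed Integer seed for the single random stream.
#' @param n_imp Imputations per repetition for `"mi"` (default 20).
#' @param level Confidence level (default 0.95).
#' @param fixed_full_data If `TRUE`, each mechanism generates its full
#'   data set once and every repetition deletes from that same data set.
#'   This is a known pitfall -- the model-based standard error then counts
#'   sampling variation that the empirical standard error cannot see --
#'   and is included so the distortion can be demonstrated and tested.
#' @param trigger Trigger rules for hybrid methods (see
#'   [hybrid_with_backup()]).
#' @param verbose Print each repetition's results as they are produced
#'   (intended for small smoke runs).
#' @return An object of class `run_plan`.
#' @export
run_plan <- function(dgm_specs, methods = c("full", "cca", "mi"),
                     n_sim = 1000L, seed, n_imp = 20L, level = 0.95,
                     fixed_full_data = FALSE,
                     trigger = default_trigger_rules(), verbose = FALSE) {
  if (inherits(dgm_specs, "dgm_spec")) dgm_specs <- list(dgm_specs)
  stopifnot(length(dgm_specs) >= 1L,
            all(vapply(dgm_specs, inherits, logical(1), "dgm_spec")))
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is mandatory: reproducibility requires an explicit seed",
         call. = FALSE)
  }
  if (anyDuplicated(methods)) stop("method labels must be unique", call. = FALSE)
  known <- c("full", "cca", "mi", "cca_firth_hybrid")
  bad <- setdiff(methods, known)
  if (length(bad)) {
    stop("unknown method label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (n_sim < 1L) stop("`n_sim` must be at least 1", call. = FALSE)
  labels <- vapply(dgm_specs, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("dgm labels must be unique", call. = FALSE)
  names(dgm_specs) <- labels
  structure(
    list(dgm_specs = dgm_specs, methods = methods, n_sim = as.integer(n_sim),
         seed = as.integer(seed), n_imp = as.integer(n_imp), level = level,
         fixed_full_data = isTRUE(fixed_full_data), trigger = trigger,
         verbose = isTRUE(verbose)),
    class = "run_plan"
  )
}

# methods whose analysis consumes random numbers
stochastic_methods <- function() "mi"

dispatch_method <- function(label, data, plan) {
  switch(
    label,
    full = analyze_complete_records(data, "all", level = plan$level),
    cca = analyze_complete_records(data, "complete_cases", level = plan$level),
    mi = analyze_mi(data, m = plan$n_imp, level = plan$level),
    cca_firth_hybrid = hybrid_with_backup(
      primary = function(d, ...) {
        analyze_complete_records(d, "complete_cases", level = plan$level,
                                 method_label = "cca_firth_hybrid")
      },
      backup = function(d, ...) {
        analyze_complete_records(d, "complete_cases", level = plan$level,
                                 method_label = "cca_firth_hybrid",
                                 engine = "firth")
      },
      data = data, trigger = plan$trigger
    ),
    stop("unknown method: ", label, call. = FALSE)
  )
}

#' Run a simulation study
#'
#' For every mechanism and repetition: capture the random-number state,
#' generate the data set, then run every method under guarded execution.
#' The random stream advances continuously across repetitions and is never
#' re-seeded inside the loop (re-seeding there is a classic bug that makes
#' consecutive repetitions produce identical data). One state is also
#' captured per repetition immediately before the first stochastic
#' analysis, so stochastic analyses (multiple imputation) can be replayed.
#'
#' @param plan A [run_plan()].
#' @return An object of class `sim_study`: a list with `estimates` (one
#'   row per dgm-method-repetition), `states` (one row per
#'   dgm-repetition, plus a `rep_id = 0` row per mechanism under
#'   `fixed_full_data`), the `plan`, and run `meta` data.
#' @examples
#' plan <- run_plan(default_dgms(), methods = c("full", "cca"),
#'                  n_sim = 3, seed = 42)
#' run <- run_study(plan)
#' tidy(run)
#' @export
run_study <- function(plan) {
  stopifnot(inherits(plan, "run_plan"))
  set.seed(plan$seed)
  est_rows <- vector("list", length(plan$dgm_specs) * plan$n_sim *
                       length(plan$methods))
  state_rows <- vector("list", length(plan$dgm_specs) * (plan$n_sim + 1L))
  ei <- si <- 0L
  stoch <- intersect(plan$methods, stochastic_methods())
  for (spec in plan$dgm_specs) {
    full0 <- NULL
    if (plan$fixed_full_data) {
      si <- si + 1L
      state_rows[[si]] <- list(rep_id = 0L, dgm = spec$label,
                               state_token = capture_state(),
                               analysis_state_token = NA_character_)
      full0 <- generate_full(spec)
    }
    for (rep in seq_len(plan$n_sim)) {
      gen_token <- capture_state()
      full <- if (plan$fixed_full_data) {
        f <- full0
        f$rep_id <- as.integer(rep)
        f
      } else {
        generate_full(spec, rep_id = rep)
      }
      data <- apply_missingness(full, spec)
      analysis_token <- NA_character_
      for (mlab in plan$methods) {
        if (mlab %in% stoch && is.na(analysis_token)) {
          analysis_token <- capture_state()
        }
        out <- run_method_guarded(function(d, ...) dispatch_method(mlab, d, plan),
                                  data, method_label = mlab)
        ei <- ei + 1L
        est_rows[[ei]] <- out
        if (plan$verbose) {
          cat(sprintf("rep %d %s/%s: status=%s estimate=%s se=%s\n",
                      rep, spec$label, mlab, out$status,
                      format(out$estimate, digits = 4),
                      format(out$se, digits = 4)))
        }
      }
      si <- si + 1L
      state_rows[[si]] <- list(rep_id = as.integer(rep), dgm = spec$label,
                               state_token = gen_token,
                               analysis_state_token = analysis_token)
    }
  }
  estimates <- dplyr::bind_rows(est_rows[seq_len(ei)])
  states <- dplyr::bind_rows(lapply(state_rows[seq_len(si)], tibble::as_tibble))
  structure(
    list(estimates = estimates, states = states, plan = plan,
         meta = list(seed = plan$seed, n_sim = plan$n_sim,
                     methods = plan$methods,
                     dgms = names(plan$dgm_specs),
                     token_format = STATE_TOKEN_FORMAT,
                     package_version = as.character(packageVersion("simtrace")))),
    class = "sim_study"
  )
}

#' @export
print.sim_study <- function(x, ...) {
  cat("<sim_study> ", length(x$plan$dgm_specs), " dgm(s) x ",
      length(x$plan$methods), " method(s) x ", x$plan$n_sim,
      " repetition(s), seed ", x$plan$seed, "\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' Tidy a simulation run
#'
#' @param x A `sim_study`.
#' @param ... Unused.
#' @return The estimates tibble: one row per dgm-method-repetition.
#' @exportS3Method generics::tidy
tidy.sim_study <- function(x, ...) x$estimates

#' Glance at a simulation run
#'
#' @param x A `sim_study`.
#' @param ... Unused.
#' @return One row per dgm-method cell: repetitions, failure and backup
#'   counts.
#' @exportS3Method generics::glance
glance.sim_study <- function(x, ...) {
  x$estimates |>
    dplyr::group_by(.data$dgm, .data$method) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_failed = sum(startsWith(.data$status, "failed")),
      n_backup = sum(.data$backup_used),
      .groups = "drop"
    )
}

#' Recreate one repetition's simulated data set
#'
#' Restores the random-number state captured just before that repetition's
#' data generation and regenerates: the result is identical, field for
#' field, to the data set analysed during the run. Under `fixed_full_data`
#' the shared full data set is first replayed from its own stored state
#' (`rep_id = 0`), then the repetition's missingness draw.
#'
#' @param states A `sim_study` object or its states tibble.
#' @param rep_id,dgm_label Which repetition of which mechanism.
#' @param plan The [run_plan()] of the original run (taken from the
#'   `sim_study` if one is supplied).
#' @return The recreated simulated data set tibble.
#' @export
recreate_dataset <- function(states, rep_id, dgm_label, plan = NULL) {
  if (inherits(states, "sim_study")) {
    plan <- states$plan
    states <- states$states
  }
  if (is.null(plan)) stop("`plan` is required when `states` is a table",
                          call. = FALSE)
  spec <- plan$dgm_specs[[dgm_label]]
  if (is.null(spec)) stop("no mechanism labelled '", dgm_label,
                          "' in the plan", call. = FALSE)
  rec <- states[states$rep_id == rep_id & states$dgm == dgm_label, ]
  if (nrow(rec) != 1L) {
    stop("no stored state for repetition ", rep_id, " of mechanism '",
         dgm_label, "'", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  if (plan$fixed_full_data) {
    rec0 <- states[states$rep_id == 0L & states$dgm == dgm_label, ]
    if (nrow(rec0) != 1L) {
      stop("fixed_full_data run but no rep_id = 0 state for mechanism '",
           dgm_label, "'", call. = FALSE)
    }
    restore_state(rec0$state_token)
    full <- generate_full(spec)
    full$rep_id <- as.integer(rep_id)
    restore_state(rec$state_token)
  } else {
    restore_state(rec$state_token)
    full <- generate_full(spec, rep_id = rep_id)
  }
  apply_missingness(full, spec)
}

#' Check that repetitions are genuinely distinct
#'
#' Two repetitions of the same mechanism and method with identical
#' (estimate, se) almost surely indicate a random-stream bug -- typically
#' code that re-sets the seed inside the repetition loop, so later
#' repetitions replay the first one's data.
#'
#' @param estimates An estimates tibble (or a `sim_study`).
#' @return An object of class `distinctness_report`: `ok` (logical) and
#'   `offending`, a tibble of duplicated repetition pairs
#'   (dgm, method, rep_a, rep_b, estimate, se).
#' @export
verify_rep_distinctness <- function(estimates) {
  if (inherits(estimates, "sim_study")) estimates <- estimates$estimates
  if (length(unique(estimates$rep_id)) < 2L) {
    stop("at least 2 repetitions are needed", call. = FALSE)
  }
  ok_rows <- estimates[!startsWith(estimates$status, "failed"), ]
  dup <- ok_rows |>
    dplyr::add_count(.data$dgm, .data$method, .data$estimate, .data$se,
                     name = "n_same") |>
    dplyr::filter(.data$n_same > 1L)
  offending <- if (nrow(dup) == 0L) {
    tibble::tibble(dgm = character(), method = character(),
                   rep_a = integer(), rep_b = integer(),
                   estimate = double(), se = double())
  } else {
    dup |>
      dplyr::summarise(
        rep_a = min(.data$rep_id), rep_b = max(.data$rep_id),
        .by = c("dgm", "method", "estimate", "se")
      ) |>
      dplyr::select("dgm", "method", "rep_a", "rep_b", "estimate", "se")
  }
  structure(list(ok = nrow(offending) == 0L, offending = offending),
            class = "distinctness_report")
}

#' @export
print.distinctness_report <- function(x, ...) {
  if (x$ok) {
    cat("<distinctness_report> OK: all repetitions distinct\n")
  } else {
    cat("<distinctness_report> FAILED: identical (estimate, se) pairs found\n")
    print(x$offending, n = 20)
  }
  invisible(x)
}
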