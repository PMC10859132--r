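# CSV round-tripping for the study's data sets (RFC 4180, UTF-8, '.'
# decimal, empty field = missing, full double precision) and the run
# configuration / metadata files.
#
# A note on a classic mistake these schemas cannot protect against: a file
# with VARIANCES stored in the `se` column (values approximately se^2) is
# schema-valid and will be read without complaint -- there is no reliable
# automatic detection. Check the scale of `se` against the width of the
# intervals before trusting external estimates files.

estimates_cols <- function() {
  readr::cols(
    rep_id = readr::col_integer(), dgm = readr::col_character(),
    method = readr::col_character(), status = readr::col_character(),
    estimate = readr::col_double(), se = readr::col_double(),
    ci_low = readr::col_double(), ci_high = readr::col_double(),
    separation = readr::col_logical(), backup_used = readr::col_logical()
  )
}

check_schema <- function(found, expected, what) {
  if (!identical(found, expected)) {
    missing <- setdiff(expected, found)
    extra <- setdiff(found, expected)
    stop(what, " schema mismatch.",
         if (length(missing)) paste0(" Missing column(s): ",
                                     paste(missing, collapse = ", "), "."),
         if (length(extra)) paste0(" Unexpected column(s): ",
                                   paste(extra, collapse = ", "), "."),
         if (!length(missing) && !length(extra)) " Columns are out of order.",
         call. = FALSE)
  }
}

#' Read and write an estimates data set
#'
#' Schema (fixed): `rep_id,dgm,method,status,estimate,se,ci_low,ci_high,`
#' `separation,backup_used`; missing values as empty fields; estimates on
#' the log-odds (estimation) scale, never exponentiated. A write-read
#' round trip is the identity.
#'
#' @param estimates An estimates tibble or `sim_study`.
#' @param path File path.
#' @return `read_estimates` returns the tibble; `write_estimates` returns
#'   `path` invisibly.
#' @export
write_estimates <- function(estimates, path) {
  if (inherits(estimates, "sim_study")) estimates <- estimates$estimates
  check_schema(names(estimates), names(estimates_cols()$cols), "estimates")
  readr::write_csv(estimates, path, na = "")
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  hdr <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                               show_col_types = FALSE))
  check_schema(hdr, names(estimates_cols()$cols), "estimates")
  readr::read_csv(path, col_types = estimates_cols(), na = "")
}

#' Read and write a states data set
#'
#' Schema: `rep_id,dgm,state_token,analysis_state_token`, tokens base64
#' encoded; the token format is versioned in a leading `#` comment line.
#'
#' @param states A states tibble or `sim_study`.
#' @param path File path.
#' @return `read_states` returns the tibble; `write_states` returns
#'   `path` invisibly.
#' @export
write_states <- function(states, path) {
  if (inherits(states, "sim_study")) states <- states$states
  expected <- c("rep_id", "dgm", "state_token", "analysis_state_token")
  check_schema(names(states), expected, "states")
  writeLines(paste0("# simtrace states; token_format=", STATE_TOKEN_FORMAT),
             path)
  readr::write_csv(states, path, na = "", append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_states
#' @export
read_states <- function(path) {
  dat <- readr::read_csv(
    path, comment = "#", na = "",
    col_types = readr::cols(
      rep_id = readr::col_integer(), dgm = readr::col_character(),
      state_token = readr::col_character(),
      analysis_state_token = readr::col_character()
    ))
  check_schema(names(dat),
               c("rep_id", "dgm", "state_token", "analysis_state_token"),
               "states")
  dat
}

#' Read and write a simulated data set
#'
#' Schema: `rep_id,dgm,C,E,D,M_C`. With `masked = TRUE`, `C` is exported
#' as an empty field wherever `M_C = 1` (the observed-data view).
#'
#' @param data A simulated data set tibble.
#' @param path File path.
#' @param masked Export the observed-`C` view (default `FALSE`).
#' @return `read_dataset` returns the tibble; `write_dataset` returns
#'   `path` invisibly.
#' @export
write_dataset <- function(data, path, masked = FALSE) {
  if (masked) data <- mask_missing(data)
  check_schema(names(data), c("rep_id", "dgm", "C", "E", "D", "M_C"),
               "simulated data set")
  readr::write_csv(data, path, na = "")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  readr::read_csv(
    path, na = "",
    col_types = readr::cols(
      rep_id = readr::col_integer(), dgm = readr::col_character(),
      C = readr::col_double(), E = readr::col_integer(),
      D = readr::col_integer(), M_C = readr::col_integer()
    ))
}

#' Read and write a performance table
#'
#' Schema: `dgm,method,measure,estimate,mcse,n_used,n_failed`.
#'
#' @param perf A [performance_table()].
#' @param path File path.
#' @return `read_performance` returns the table; `write_performance`
#'   returns `path` invisibly.
#' @export
write_performance <- function(perf, path) {
  check_schema(names(perf), c("dgm", "method", "measure", "estimate",
                              "mcse", "n_used", "n_failed"),
               "performance table")
  readr::write_csv(perf, path, na = "")
  invisible(path)
}

#' @rdname write_performance
#' @export
read_performance <- function(path) {
  res <- readr::read_csv(
    path, na = "",
    col_types = readr::cols(
      dgm = readr::col_character(), method = readr::col_character(),
      measure = readr::col_character(), estimate = readr::col_double(),
      mcse = readr::col_double(), n_used = readr::col_integer(),
      n_failed = readr::col_integer()
    ))
  class(res) <- c("performance_table", class(res))
  res
}

#' Write zip-plot data
#'
#' Schema: `dgm,method,rep_id,rank_fraction,p_value,ci_low,ci_high,covers`.
#'
#' @param zip Output of [zip_plot_data()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_zip_data <- function(zip, path) {
  check_schema(names(zip), c("dgm", "method", "rep_id", "rank_fraction",
                             "p_value", "ci_low", "ci_high", "covers"),
               "zip data")
  readr::write_csv(zip, path, na = "")
  invisible(path)
}

#' Write run metadata
#'
#' JSON with the seed, a plan echo, the package version and a timestamp.
#'
#' @param run A `sim_study`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_run_meta <- function(run, path) {
  plan <- run$plan
  meta <- list(
    seed = plan$seed,
    n_sim = plan$n_sim,
    n_imp = plan$n_imp,
    level = plan$level,
    methods = plan$methods,
    fixed_full_data = plan$fixed_full_data,
    dgms = lapply(plan$dgm_specs, function(s) unclass(s)),
    trigger = plan$trigger,
    token_format = STATE_TOKEN_FORMAT,
    package_version = as.character(packageVersion("simtrace")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
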