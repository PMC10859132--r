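# Run configuration: one YAML (or JSON) document mirroring run_plan plus
# the method settings. Unknown keys are rejected -- a silently ignored
# misspelt key is exactly the kind of error a simulation study cannot
# afford.

config_known_keys <- function() {
  c("seed", "n_sim", "n_imp", "level", "alpha", "methods",
    "fixed_full_data", "verbose", "dgms", "trigger", "outliers")
}

dgm_known_keys <- function() {
  c("label", "mechanism", "n_obs", "alpha0", "alphaC", "beta0", "betaE",
    "betaC", "gamma0", "gammaE", "gammaD", "gammaC")
}

reject_unknown <- function(keys, known, where) {
  bad <- setdiff(keys, known)
  if (length(bad)) {
    stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
}

#' Read a run configuration
#'
#' Parses a YAML (or JSON) run configuration into a [run_plan()] plus the
#' method settings. Every field defaults to the package default; unknown
#' keys are rejected. Top-level keys: `seed` (mandatory), `n_sim`,
#' `n_imp`, `level`, `alpha`, `methods`, `fixed_full_data`, `verbose`,
#' `dgms` (a list of [dgm_spec()] field sets; default: the three default
#' mechanisms), `trigger`, `outliers`.
#'
#' @param path Path to the YAML/JSON file.
#' @return A list with `plan` (a `run_plan`), `alpha`, `outlier_rules`,
#'   and the raw `config` echo.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  reject_unknown(names(cfg), config_known_keys(), "config")
  if (is.null(cfg$seed)) stop("config must set `seed`", call. = FALSE)
  specs <- if (is.null(cfg$dgms)) {
    default_dgms()
  } else {
    lapply(cfg$dgms, function(d) {
      reject_unknown(names(d), dgm_known_keys(), paste0("dgm '", d$label, "'"))
      do.call(dgm_spec, d)
    })
  }
  trig <- default_trigger_rules()
  if (!is.null(cfg$trigger)) {
    reject_unknown(names(cfg$trigger), names(trig), "trigger")
    trig[names(cfg$trigger)] <- cfg$trigger
  }
  outl <- default_outlier_rules()
  if (!is.null(cfg$outliers)) {
    reject_unknown(names(cfg$outliers), names(outl), "outliers")
    outl[names(cfg$outliers)] <- cfg$outliers
  }
  plan <- run_plan(
    dgm_specs = specs,
    methods = cfg$methods %||% c("full", "cca", "mi"),
    n_sim = cfg$n_sim %||% 1000L,
    seed = cfg$seed,
    n_imp = cfg$n_imp %||% 20L,
    level = cfg$level %||% 0.95,
    fixed_full_data = cfg$fixed_full_data %||% FALSE,
    trigger = trig,
    verbose = cfg$verbose %||% FALSE
  )
  list(plan = plan, alpha = cfg$alpha %||% 0.05, outlier_rules = outl,
       config = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
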