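# Unified pipeline entry point: one validated config describes a complete
# run (simulate / regress / fit / optimize / recover); every artifact is
# written next to a provenance record sufficient to regenerate it.

#' Load a pipeline configuration
#'
#' @param path YAML or JSON file mirroring the [run_pipeline()] config list.
#' @return Named list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config '%s' not found", path))
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- load_config(config)
  if (!is.list(config)) abort("config must be a list or a path to one")
  cmd <- config$command
  if (is.null(cmd) || !cmd %in% c("simulate", "regress", "fit", "optimize",
                                  "recover")) {
    abort("config field 'command' must be one of simulate/regress/fit/optimize/recover")
  }
  if (is.null(config$out)) abort("config field 'out' (output directory) is required")
  need <- switch(cmd,
    simulate = c("agent"),
    regress = c("sessions"),
    fit = c("model", "sessions"),
    optimize = c("model", "condition"),
    recover = character(0))
  missing <- setdiff(need, names(config))
  if (length(missing) > 0L) {
    abort(sprintf("config for '%s' is missing field(s): %s", cmd,
                  paste(missing, collapse = ", ")))
  }
  config
}

#' Run a configured analysis pipeline
#'
#' Commands:
#' \describe{
#'   \item{`simulate`}{closed-loop sessions of `agent` (with optional
#'     `params`) on `schedule` (protocol name, default `"mouse"`) for
#'     `n_sessions` (default 1); writes session CSVs.}
#'   \item{`regress`}{history regression (`n_lags`, `extended`) on sessions
#'     read from `sessions`; writes tidy coefficients CSV and a fit JSON.}
#'   \item{`fit`}{[anneal_fit()] of `model` on `sessions`; writes a fit
#'     JSON (optionally cross-validated when `folds` is given).}
#'   \item{`optimize`}{[optimize_in_env()] of `model` under `condition`
#'     (list with `type`, and `block_length`/`pair`); writes JSON and the
#'     implied trace-shape CSV for DT parameters.}
#'   \item{`recover`}{[generate_recovery_dataset()] for `true_params` (or
#'     random draws when absent, `n_draws`); writes CSVs and manifest.}
#' }
#' Every run writes `provenance.json` (config echo, seed, package version,
#' timings).
#'
#' @param config Named list or path to a YAML/JSON config.
#' @return Invisibly, a list of artifact paths.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  t0 <- Sys.time()
  out_dir <- config$out
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  paths <- character(0)
  cmd <- config$command
  if (cmd == "simulate") {
    agent <- do.call(vi_agent, c(list(model = config$agent),
                                 as.list(config$params)))
    sessions <- run_sessions(agent, config$schedule %||% "mouse",
                             config$n_sessions %||% 1L, seed = seed)
    paths <- write_sessions(sessions, out_dir)
  } else if (cmd == "regress") {
    sessions <- read_sessions(config$sessions)
    fit <- fit_history_glm(sessions,
                           n_lags = config$n_lags %||%
                             if (isTRUE(config$extended)) 30 else 15,
                           extended = isTRUE(config$extended), seed = seed)
    coef_path <- file.path(out_dir, "coefficients.csv")
    write.csv(tidy(fit), coef_path, row.names = FALSE)
    fit_path <- file.path(out_dir, "regression.json")
    jsonlite::write_json(
      list(lambda = fit$lambda, intercept = fit$intercept,
           coefficients = fit$coef, cv_deviance = fit$cv_deviance),
      fit_path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
    paths <- c(coef_path, fit_path)
  } else if (cmd == "fit") {
    sessions <- read_sessions(config$sessions)
    fit_path <- file.path(out_dir, "fit.json")
    if (!is.null(config$folds)) {
      cv <- crossval_compare(config$model, sessions,
                             n_folds = config$folds,
                             n_draws = config$n_draws %||% 1000,
                             seed = seed)
      jsonlite::write_json(
        list(model = config$model, mean_test_nll = cv$mean_test_nll,
             mean_test_auc = cv$mean_test_auc),
        fit_path, auto_unbox = TRUE, digits = NA)
    } else {
      fit <- anneal_fit(config$model, sessions,
                        n_draws = config$n_draws %||% 1000, seed = seed)
      jsonlite::write_json(
        list(model = fit$model, theta_hat = as.list(fit$theta_hat),
             logLik = fit$logLik, converged = fit$converged),
        fit_path, auto_unbox = TRUE, digits = NA)
    }
    paths <- fit_path
  } else if (cmd == "optimize") {
    cond <- config$condition
    condition <- harvest_condition(cond$type,
                                   block_length = cond$block_length %||% 100,
                                   pair = cond$pair,
                                   n_trials = config$n_trials %||% 1000)
    opt <- optimize_in_env(config$model, condition,
                           n_initial = config$n_initial %||% 10000,
                           n_refine = config$n_refine %||% 5000,
                           n_retest = config$n_retest %||% 100,
                           n_sessions = config$n_sessions %||% 4,
                           seed = seed)
    opt_path <- file.path(out_dir, "optimize.json")
    jsonlite::write_json(
      list(model = opt$model, condition = opt$condition,
           theta_star = as.list(opt$theta_star),
           mean_regret = opt$mean_regret),
      opt_path, auto_unbox = TRUE, digits = NA)
    paths <- opt_path
    if (config$model == "dt") {
      ts_path <- file.path(out_dir, "trace_shapes.csv")
      write.csv(trace_shapes(opt$theta_star), ts_path, row.names = FALSE)
      paths <- c(paths, ts_path)
    }
  } else if (cmd == "recover") {
    tp <- config$true_params %||%
      as.list(random_dt_params(1, seed = seed)[1, ])
    res <- generate_recovery_dataset(tp,
                                     n_sessions = config$n_sessions %||% 20L,
                                     seed = seed)
    paths <- write_sessions(res$sessions, out_dir)
    man_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(res$manifest, man_path, auto_unbox = TRUE,
                         digits = NA)
    paths <- c(paths, man_path)
  }
  prov_path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(
    list(config = config, seed = seed,
         package = list(name = "vitrace",
                        version = as.character(packageVersion("vitrace"))),
         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
         timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z")),
    prov_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, prov_path))
}
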