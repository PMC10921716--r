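# Orchestration of the two headline experiments, plus config I/O and a
# small command-line front end (inst/cli/bioagesim).

#' Experiment configuration
#'
#' @param experiment one of `"example1"`, `"scenario"`, `"cohort"`.
#' @param params generator parameter object ([sim_params1],
#'   [scenario_table] or [lls_params]); a default is built when `NULL`.
#' @param methods methods to run. Scenario experiment: subset of
#'   `c("mlr", "kd", "equal")`. Cohort experiment: fixed to the four-method
#'   design (ridge, mlr, equal, random).
#' @param replicates number of replicate data sets.
#' @param seed base seed; replicate r uses `seed + r - 1` (a unique seed
#'   sequence).
#' @param n_draws random-weight draws for the cohort experiment.
#' @param scenarios scenario labels for the scenario experiment.
#' @param output_dir optional directory for CSV/JSON side outputs.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(experiment = c("scenario", "cohort", "example1"),
                              params = NULL,
                              methods = c("mlr", "kd", "equal"),
                              replicates = 1, seed = 1, n_draws = 1000,
                              scenarios = c("A", "B", "C", "D"),
                              output_dir = NULL) {
  experiment <- match.arg(experiment)
  replicates <- check_count(replicates, "replicates", lower = 1L)
  n_draws <- check_count(n_draws, "n_draws", lower = 1L)
  bad <- setdiff(scenarios, c("A", "B", "C", "D"))
  if (length(bad)) stop("unknown scenario label(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  bad_m <- setdiff(methods, c("mlr", "kd", "equal"))
  if (length(bad_m)) stop("unknown method(s): ",
                          paste(bad_m, collapse = ", "), call. = FALSE)
  if (is.null(params)) {
    params <- switch(experiment,
                     example1 = sim_params1(),
                     scenario = scenario_table(),
                     cohort = lls_params())
  }
  seeds <- as.integer(seed) + seq_len(replicates) - 1L
  structure(list(experiment = experiment, params = params, methods = methods,
                 replicates = replicates, seed = as.integer(seed),
                 seeds = seeds, n_draws = n_draws, scenarios = scenarios,
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Run the four-scenario recovery experiment
#'
#' For each replicate and scenario: generate the three-marker cohort, fit
#' the requested predictor families (MLR, Klemera-Doubal, equal weights
#' derived from MLR), extract the divergence prediction, and score recovery
#' against the simulated truth.
#'
#' @param config an [experiment_config] with `experiment = "scenario"`.
#' @return list of class `scenario_experiment`: `results` (tidy data.frame,
#'   one row per replicate x scenario x method with `pearson_r`, `rmse`,
#'   `slope`), `summary` (per scenario x method means), `panel` (per-subject
#'   truth vs prediction of replicate 1, for plotting), `config_hash`,
#'   `seeds`.
#' @export
run_scenario_experiment <- function(config = experiment_config("scenario")) {
  stopifnot(inherits(config, "experiment_config"),
            config$experiment == "scenario")
  tab <- config$params
  stopifnot(inherits(tab, "scenario_table"))
  rows <- list()
  panel <- list()
  for (r in seq_len(config$replicates)) {
    tab$seed <- config$seeds[r]
    for (sc in config$scenarios) {
      dat <- gen_example2(tab, sc)
      mlr <- fit_mlr(dat)
      preds <- list()
      if ("mlr" %in% config$methods) preds$mlr <- predict_delta(mlr, dat)
      if ("kd" %in% config$methods) preds$kd <- predict_delta(fit_kd(dat), dat)
      if ("equal" %in% config$methods) {
        preds$equal <- predict_delta(make_equal_weights(mlr), dat)
      }
      for (mth in names(preds)) {
        met <- eval_delta_recovery(preds[[mth]], dat$delta)
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = r, scenario = sc, method = mth,
          pearson_r = met$pearson_r, rmse = met$rmse, slope = met$slope)
        if (r == 1L) {
          panel[[length(panel) + 1L]] <- data.frame(
            scenario = sc, method = mth, delta = dat$delta,
            delta_hat = preds[[mth]]$delta_hat)
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(cbind(pearson_r, rmse, slope) ~ scenario + method,
                              data = results, FUN = mean)
  out <- structure(list(results = results, summary = summary,
                        panel = do.call(rbind, panel),
                        seeds = config$seeds,
                        config_hash = config_hash(strip_config(config))),
                   class = "scenario_experiment")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results, file.path(config$output_dir, "scenario_results.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(config$output_dir, "scenario_summary.csv"),
                     row.names = FALSE)
  }
  out
}

#' Run the cohort mortality-association experiment
#'
#' The four-method design on a survival cohort: (1) ridge with 10-fold
#' cross-validation on all markers; (2) OLS on the Bonferroni-preselected
#' subset; (3) equal weights derived from (2); (4) `n_draws` sign-preserving
#' uniform random-weight combinations of the same subset. Each method's
#' divergence prediction is z-scored and entered into a left-truncated Cox
#' model on the age timescale (adjusted for sex). The age-prediction RMSE of
#' methods 1 and 2 is reported alongside, to expose the biomarker-paradox
#' contrast (better age prediction need not mean stronger mortality
#' association of the residual).
#'
#' @param config an [experiment_config] with `experiment = "cohort"`.
#' @param data optional [cohort_data] with survival fields; when missing the
#'   cohort is generated from `config$params` via [gen_lls_like].
#' @return list of class `cohort_experiment`: `cox_table` (one row per
#'   method: logHR per sd, se, events), `random_summary`
#'   ([summarize_random_coefs] of the draws vs methods 1-3), `rmse` (named:
#'   ridge, mlr), `n_selected`, `log` (stage record counts), `config_hash`,
#'   `seeds`.
#' @export
run_cohort_experiment <- function(config = experiment_config("cohort"),
                                  data = NULL) {
  stopifnot(inherits(config, "experiment_config"),
            config$experiment == "cohort")
  if (is.null(data)) {
    p <- config$params
    stopifnot(inherits(p, "lls_params"))
    p$seed <- config$seeds[1L]
    data <- gen_lls_like(p)
  }
  if (is.null(data$event)) stop("cohort lacks survival columns", call. = FALSE)

  ridge <- fit_ridge_cv(data, folds = 10, seed = config$seeds[1L])
  sel <- preselect_markers(data, alpha_fw = 0.05)
  if (!length(sel)) stop("no markers survive pre-selection", call. = FALSE)
  mlr <- fit_mlr(data, names(sel))
  equal <- make_equal_weights(mlr)
  draws <- sample_random_weights(sign(mlr$weights), n_draws = config$n_draws,
                                 seed = config$seeds[1L] + 10000L)

  pred <- list(ridge = predict_delta(ridge, data),
               mlr = predict_delta(mlr, data),
               equal = predict_delta(equal, data))
  cox <- lapply(pred, fit_cox_delta, data = data)
  cox_draws <- lapply(draws, function(m) fit_cox_delta(predict_delta(m, data), data))

  cox_table <- do.call(rbind, lapply(names(cox), function(nm) {
    r <- cox[[nm]]
    data.frame(method = nm, loghr_per_sd = r$loghr_per_sd, se = r$se,
               n_events = r$n_events, n_subjects = r$n_subjects)
  }))
  refs <- stats::setNames(cox_table$loghr_per_sd, cox_table$method)
  random_summary <- summarize_random_coefs(cox_draws, refs)

  out <- structure(list(
    cox_table = cox_table,
    random_summary = random_summary,
    random_coefs = random_summary$coefs,
    rmse = c(ridge = rmse_age(pred$ridge$proxy, data$age),
             mlr = rmse_age(pred$mlr$proxy, data$age)),
    n_selected = length(sel),
    models = list(ridge = ridge, mlr = mlr, equal = equal),
    log = c(n_subjects = nrow(data), n_markers = length(marker_names(data)),
            n_selected = length(sel), n_events = sum(data$event),
            n_draws = config$n_draws),
    seeds = config$seeds,
    config_hash = config_hash(strip_config(config))),
    class = "cohort_experiment")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cox_table, file.path(config$output_dir, "cox_table.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(draw = seq_along(random_summary$coefs),
                 loghr_per_sd = random_summary$coefs),
      file.path(config$output_dir, "random_coefs.csv"), row.names = FALSE)
  }
  out
}

#' @export
print.cohort_experiment <- function(x, ...) {
  cat("<cohort_experiment>\n")
  print(x$cox_table, row.names = FALSE)
  cat(sprintf("  RMSE(age): ridge %.2f, mlr %.2f; %d/%d markers selected\n",
              x$rmse["ridge"], x$rmse["mlr"], x$n_selected,
              x$log["n_markers"]))
  cat(sprintf("  random draws: median %.4f; P(draw > ridge) = %.3f\n",
              x$random_summary$median, x$random_summary$exceedance["ridge"]))
  invisible(x)
}

# drop non-serializable members before hashing
strip_config <- function(config) {
  config$output_dir <- NULL
  unclass_deep <- function(x) {
    if (is.list(x)) lapply(unclass(x), unclass_deep) else x
  }
  unclass_deep(config)
}

#' Read a generator/experiment config file
#'
#' JSON (recommended) or a flat YAML-like subset: one `key: value` pair per
#' line, `#` comments, numbers and the literals true/false parsed; values
#' containing commas become numeric/character vectors. Nested blocks are not
#' supported in the YAML subset — use JSON for structured configs.
#'
#' @param path file path (`.json` or `.yml`/`.yaml`/`.txt`).
#' @return named list of values.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    return(jsonlite::fromJSON(path, simplifyVector = TRUE))
  }
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("cannot parse config line: ", ln, call. = FALSE)
    key <- m[2]
    val <- trimws(strsplit(m[3], ",")[[1]])
    parse1 <- function(v) {
      if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else v
    }
    vals <- lapply(val, parse1)
    out[[key]] <- if (length(vals) == 1L) vals[[1]] else unlist(vals)
  }
  out
}
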