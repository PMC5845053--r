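# End-to-end run orchestration: simulate (or load) -> fit -> covariate
# search -> bootstrap -> VPC -> consolidated report. Every stage gets its
# own RNG stream derived from the master seed, so toggling one stage never
# shifts another stage's draws; rerunning a configuration reproduces every
# numeric output.

#' Default pipeline configuration
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "fit", "covsearch", "bootstrap", "vpc")` (the report is
#'   always written).
#' @param data path to an existing event-table CSV (used when
#'   `"simulate"` is not among the stages).
#' @param cohort list of [cohort_config()] overrides for the simulate
#'   stage.
#' @param model list of [poppk_model()] arguments for the initial model.
#' @param method estimation method passed to [poppk()].
#' @param covsearch list of [covariate_search()] argument overrides.
#' @param bootstrap list with `n_reps` (and other [poppk_bootstrap()]
#'   arguments).
#' @param vpc list with `n_sim`, `n_bins` (and other [poppk_vpc()]
#'   arguments).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = c("simulate", "fit", "covsearch",
                                       "bootstrap", "vpc"),
                            data = NULL, cohort = list(), model = list(),
                            method = "foce", covsearch = list(),
                            bootstrap = list(n_reps = 200L),
                            vpc = list(n_sim = 500L, n_bins = 10L)) {
  structure(list(seed = as.integer(seed), stages = stages, data = data,
                 cohort = cohort, model = model, method = method,
                 covsearch = covsearch, bootstrap = bootstrap, vpc = vpc),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return a `pipeline_config`.
#' @export
read_run_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

stage_seed <- function(master, k) (master * 10L + k) %% 2000000000L

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order, writing one artifact per stage
#' under `dir` (`data.csv`, `fit.json`, `covsearch.csv`, `bootstrap.csv`
#' and `bootstrap_summary.csv`, `vpc.csv`) plus a consolidated
#' `report.json` mirroring the standard parameter-table layout (estimate,
#' \%RSE, shrinkage per parameter, variances also on both \%CV
#' conventions) and a `log.txt` recording each stage with its seed and
#' settings. A stage failure halts downstream stages; artifacts already
#' written are preserved.
#'
#' @param config a [pipeline_config()] (or YAML path).
#' @param dir output directory, created if needed.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), dir = "poppk_run") {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(dir, "log.txt")
  cat("", file = logf)
  logmsg <- function(...) cat(sprintf(...), "\n", sep = "", file = logf, append = TRUE)
  results <- list(config = config)
  logmsg("run_pipeline master seed %d; stages: %s", config$seed,
         paste(config$stages, collapse = ", "))
  run_stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      logmsg("stage %s FAILED: %s", name, conditionMessage(e))
      stop("stage ", name, " failed: ", conditionMessage(e),
           " (partial artifacts preserved in ", dir, ")", call. = FALSE)
    })
    logmsg("stage %s done", name)
    out
  }

  if ("simulate" %in% config$stages) {
    sseed <- stage_seed(config$seed, 1L)
    logmsg("simulate: seed %d, overrides: %s", sseed,
           paste(names(config$cohort), collapse = ", ") )
    tab <- run_stage("simulate", {
      cc <- do.call(cohort_config, config$cohort)
      simulate_cohort(cc, seed = sseed)
    })
    write_event_table(tab, file.path(dir, "data.csv"))
    results$data <- tab
  } else {
    if (is.null(config$data)) stop_invalid("no simulate stage and no data path")
    results$data <- run_stage("load", read_event_table(config$data))
  }

  if ("fit" %in% config$stages) {
    logmsg("fit: method %s", config$method)
    fit <- run_stage("fit", {
      init <- do.call(poppk_model, config$model)
      poppk(results$data, model = init, method = config$method)
    })
    results$fit <- fit
    jsonlite::write_json(fit_report(fit), file.path(dir, "fit.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  }

  if ("covsearch" %in% config$stages && !is.null(results$fit)) {
    logmsg("covsearch: thresholds %.4f / %.4f",
           config$covsearch$forward_threshold %||% selection_thresholds()[["forward"]],
           config$covsearch$backward_threshold %||% selection_thresholds()[["backward"]])
    cs <- run_stage("covsearch",
      do.call(covariate_search, c(list(results$fit), config$covsearch)))
    results$covsearch <- cs
    write_search_trace(cs, file.path(dir, "covsearch.csv"))
  }

  if ("bootstrap" %in% config$stages && !is.null(results$fit)) {
    bseed <- stage_seed(config$seed, 3L)
    nb <- config$bootstrap$n_reps %||% 200L
    logmsg("bootstrap: seed %d, n_reps %d", bseed, nb)
    bs <- run_stage("bootstrap", {
      args <- config$bootstrap; args$n_reps <- nb
      do.call(poppk_bootstrap, c(list(results$fit, seed = bseed), args))
    })
    results$bootstrap <- bs
    write_bootstrap(bs, file.path(dir, "bootstrap.csv"))
    write.csv(bs$summary, file.path(dir, "bootstrap_summary.csv"), row.names = FALSE)
  }

  if ("vpc" %in% config$stages && !is.null(results$fit)) {
    vseed <- stage_seed(config$seed, 4L)
    logmsg("vpc: seed %d, n_sim %d", vseed, config$vpc$n_sim %||% 500L)
    vp <- run_stage("vpc",
      do.call(poppk_vpc, c(list(results$fit, seed = vseed), config$vpc)))
    results$vpc <- vp
    write_vpc(vp, file.path(dir, "vpc.csv"))
  }

  report <- list(seed = config$seed, stages = config$stages)
  if (!is.null(results$fit)) report$fit <- fit_report(results$fit)
  if (!is.null(results$covsearch))
    report$covariates_selected <- lapply(results$covsearch$selected, function(s)
      list(parameter = s$parameter, covariate = s$covariate, form = s$form,
           beta = s$beta))
  if (!is.null(results$bootstrap))
    report$bootstrap <- c(list(n_requested = results$bootstrap$n_requested,
                               n_converged = results$bootstrap$n_converged),
                          list(summary = results$bootstrap$summary))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  logmsg("report written")
  invisible(results)
}

# structured parameter report mirroring the standard population-PK table:
# estimate (%RSE) [shrinkage], variances also on both %CV conventions
fit_report <- function(fit) {
  s <- summary(fit)
  list(method = fit$method, ofv = fit$ofv, converged = fit$converged,
       n_subjects = s$n_subjects, n_obs = s$n_obs,
       parameters = s$table)
}
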