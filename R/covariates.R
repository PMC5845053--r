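# Stepwise covariate model building: eta-shrinkage-gated screening, forward
# selection at the chi-square(1) 5% point (OFV must drop by more than 3.84)
# and backward elimination at the 1% point (a term is kept only if removing
# it raises OFV by more than 6.63).

#' Likelihood-ratio selection thresholds
#'
#' Chi-square(1) quantiles used by the stepwise search.
#'
#' @param p_forward,p_backward significance levels for inclusion and
#'   retention.
#' @return named vector `c(forward, backward)`; at the defaults, 3.84 and
#'   6.63 to two decimals.
#' @export
selection_thresholds <- function(p_forward = 0.05, p_backward = 0.01) {
  c(forward = qchisq(1 - p_forward, df = 1),
    backward = qchisq(1 - p_backward, df = 1))
}

#' Screen parameters for covariate modelling
#'
#' Covariate relationships are only explored on parameters whose
#' eta-shrinkage is strictly below the threshold; above it the empirical
#' Bayes estimates are too shrunken to be informative.
#'
#' @param fit a converged [poppk()] fit.
#' @param shrinkage_threshold percent threshold (default 25).
#' @return character vector of eligible parameter names.
#' @export
screen_parameters <- function(fit, shrinkage_threshold = 25) {
  stopifnot(inherits(fit, "poppk"))
  shr <- fit$shrinkage
  shr <- shr[names(fit$model$omega2)[fit$model$omega2 > 0]]
  if (length(shr) == 0) return(character(0))
  if (anyNA(shr)) {
    warning("shrinkage missing for ", paste(names(shr)[is.na(shr)], collapse = ", "),
            "; excluded from screening")
  }
  names(shr)[!is.na(shr) & shr < shrinkage_threshold]
}

#' Add a covariate term to a model
#'
#' @param model a [poppk_model()].
#' @param spec a [covariate_term()].
#' @return the model with the term appended (`beta = 0` reproduces the base
#'   model exactly).
#' @export
apply_covariate <- function(model, spec) {
  spec <- as_covariate_term(spec)
  poppk_model(theta = model$theta, omega2 = model$omega2, sigma2 = model$sigma2,
              ncomp = model$ncomp, error = model$error,
              covariates = c(model$covariates, list(spec)))
}

drop_covariate <- function(model, index) {
  poppk_model(theta = model$theta, omega2 = model$omega2, sigma2 = model$sigma2,
              ncomp = model$ncomp, error = model$error,
              covariates = model$covariates[-index])
}

# candidate grid: one row per (parameter, covariate, form)
candidate_grid <- function(parameters, covariates, data,
                           forms = c("both", "linear", "power")) {
  forms <- match.arg(forms)
  cov_df <- data$covariates
  out <- list()
  for (cv in covariates) {
    x <- cov_df[[cv]]
    if (is.null(x)) stop_invalid("covariate ", cv, " not in the data")
    categorical <- length(unique(x)) <= 2
    ref <- if (categorical) NULL else median(x)
    fms <- if (categorical) "indicator"
           else if (forms == "both") c("linear", "power") else forms
    for (pm in parameters) for (fm in fms)
      out[[length(out) + 1L]] <- list(parameter = pm, covariate = cv,
                                      form = fm, ref = ref)
  }
  out
}

refit_with <- function(fit, model, control) {
  poppk(fit$data, model = model, method = fit$method, control = control)
}

trace_row <- function(step, phase, cand, ofv, delta, decision) {
  data.frame(step = step, phase = phase,
             parameter = cand$parameter %||% NA_character_,
             covariate = cand$covariate %||% NA_character_,
             form = cand$form %||% NA_character_,
             ofv = ofv, delta_ofv = delta, decision = decision,
             stringsAsFactors = FALSE)
}

#' Stepwise forward selection of covariate effects
#'
#' At each step every remaining candidate is added (alone) to the current
#' model and refitted; the candidate with the largest OFV drop is included
#' if the drop exceeds the threshold; the process repeats until no
#' candidate qualifies. Candidates sharing a (parameter, covariate) pair
#' (e.g. linear and power forms) compete first among themselves, best form
#' wins. Exact ties are broken by candidate order.
#'
#' @param fit the base [poppk()] fit.
#' @param candidates list of candidate descriptors from the internal grid
#'   builder, or of [covariate_term()] specifications.
#' @param threshold minimum OFV drop for inclusion (3.84 = chi-square(1)
#'   at p 0.05).
#' @param control fitting control for candidate fits (standard errors off
#'   by default).
#' @return list of class `covsearch_trace`: `trace` data frame (one row per
#'   candidate fit with OFV, delta-OFV and decision), `fit` (final fit),
#'   `included` (list of included terms).
#' @export
forward_selection <- function(fit, candidates, threshold = selection_thresholds()[["forward"]],
                              control = poppk_control(se = FALSE)) {
  stopifnot(inherits(fit, "poppk"))
  current <- fit
  included <- list()
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    taken_keys <- vapply(current$model$covariates,
                         function(s) paste(s$parameter, s$covariate), "")
    open <- Filter(function(cand)
      !paste(cand$parameter, cand$covariate) %in% taken_keys, candidates)
    if (length(open) == 0) break
    keys <- vapply(open, function(cand) paste(cand$parameter, cand$covariate), "")
    best <- NULL
    for (key in unique(keys)) {
      forms <- open[keys == key]
      key_best <- NULL
      for (cand in forms) {
        spec <- covariate_term(cand$parameter, cand$covariate, cand$form,
                               beta = 0, ref = cand$ref)
        cf <- tryCatch(refit_with(current, apply_covariate(current$model, spec), control),
                       error = function(e) NULL)
        if (is.null(cf) || !cf$converged) {
          trace[[length(trace) + 1L]] <-
            trace_row(step, "forward", cand, NA_real_, NA_real_, "skipped (non-convergence)")
          next
        }
        delta <- current$ofv - cf$ofv
        trace[[length(trace) + 1L]] <-
          trace_row(step, "forward", cand, cf$ofv, delta, "tested")
        if (is.null(key_best) || delta > key_best$delta)
          key_best <- list(fit = cf, delta = delta, cand = cand)
      }
      if (!is.null(key_best) && (is.null(best) || key_best$delta > best$delta))
        best <- key_best
    }
    if (is.null(best) || best$delta <= threshold) break
    current <- best$fit
    included[[length(included) + 1L]] <- best$cand
    trace[[length(trace) + 1L]] <-
      trace_row(step, "forward", best$cand, best$fit$ofv, best$delta, "included")
  }
  structure(list(trace = do.call(rbind, trace) %||% empty_trace(),
                 fit = current, included = included),
            class = "covsearch_trace")
}

empty_trace <- function() {
  data.frame(step = integer(0), phase = character(0), parameter = character(0),
             covariate = character(0), form = character(0), ofv = numeric(0),
             delta_ofv = numeric(0), decision = character(0),
             stringsAsFactors = FALSE)
}

#' Backward elimination of covariate effects
#'
#' Iteratively removes the included term whose removal increases OFV the
#' least, whenever that increase is below the threshold; stops when every
#' remaining removal costs more.
#'
#' @param fit the full-model [poppk()] fit from the forward phase.
#' @param threshold maximum tolerated OFV increase for removal (6.63 =
#'   chi-square(1) at p 0.01).
#' @param control fitting control for candidate fits.
#' @return list of class `covsearch_trace` (see [forward_selection()]).
#' @export
backward_elimination <- function(fit, threshold = selection_thresholds()[["backward"]],
                                 control = poppk_control(se = FALSE)) {
  stopifnot(inherits(fit, "poppk"))
  current <- fit
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    terms <- current$model$covariates
    if (length(terms) == 0) break
    best <- NULL
    for (j in seq_along(terms)) {
      cand <- terms[[j]]
      cf <- tryCatch(refit_with(current, drop_covariate(current$model, j), control),
                     error = function(e) NULL)
      if (is.null(cf) || !cf$converged) {
        trace[[length(trace) + 1L]] <-
          trace_row(step, "backward", cand, NA_real_, NA_real_, "skipped (non-convergence)")
        next
      }
      delta <- cf$ofv - current$ofv   # cost of removal
      trace[[length(trace) + 1L]] <-
        trace_row(step, "backward", cand, cf$ofv, delta, "tested")
      if (is.null(best) || delta < best$delta)
        best <- list(fit = cf, delta = delta, cand = cand)
    }
    if (is.null(best) || best$delta >= threshold) break
    current <- best$fit
    trace[[length(trace) + 1L]] <-
      trace_row(step, "backward", best$cand, best$fit$ofv, best$delta, "removed")
  }
  structure(list(trace = do.call(rbind, trace) %||% empty_trace(),
                 fit = current, included = current$model$covariates),
            class = "covsearch_trace")
}

#' Full stepwise covariate search
#'
#' Shrinkage-gated screening followed by forward selection and backward
#' elimination. Continuous covariates are tried with both linear and power
#' forms (best form competes); binary covariates with an indicator form.
#' Reference values default to the in-sample covariate medians so typical
#' values keep their typical-patient interpretation.
#'
#' @param fit the base [poppk()] fit.
#' @param covariates covariate column names to consider.
#' @param parameters parameters to consider; defaults to those passing the
#'   shrinkage screen.
#' @param shrinkage_threshold percent shrinkage gate (default 25).
#' @param forward_threshold,backward_threshold OFV thresholds (defaults
#'   3.84 and 6.63).
#' @param forms `"both"` (default), `"linear"` or `"power"` for continuous
#'   covariates.
#' @param control fitting control for candidate fits.
#' @return object of class `covsearch`: `screened`, `trace` (full search
#'   log), `fit` (final model fit), `selected` (covariate terms retained).
#' @export
covariate_search <- function(fit,
                             covariates = c("WT", "AGE", "DUR", "SEX", "SOFA", "INOTR"),
                             parameters = NULL, shrinkage_threshold = 25,
                             forward_threshold = selection_thresholds()[["forward"]],
                             backward_threshold = selection_thresholds()[["backward"]],
                             forms = "both",
                             control = poppk_control(se = FALSE)) {
  stopifnot(inherits(fit, "poppk"))
  screened <- screen_parameters(fit, shrinkage_threshold)
  parameters <- parameters %||% screened
  parameters <- intersect(parameters, screened)
  if (length(parameters) == 0 || length(covariates) == 0) {
    return(structure(list(screened = screened, trace = empty_trace(),
                          fit = fit, selected = list()),
                     class = "covsearch"))
  }
  cands <- candidate_grid(parameters, covariates, fit$data, forms)
  fwd <- forward_selection(fit, cands, forward_threshold, control)
  bwd <- backward_elimination(fwd$fit, backward_threshold, control)
  structure(list(screened = screened,
                 trace = rbind(fwd$trace, bwd$trace),
                 fit = bwd$fit, selected = bwd$fit$model$covariates),
            class = "covsearch")
}

#' @export
print.covsearch <- function(x, ...) {
  cat("Stepwise covariate search\n")
  cat("  screened parameters:",
      if (length(x$screened)) paste(x$screened, collapse = ", ") else "(none)", "\n")
  if (length(x$selected) == 0) cat("  no covariates selected\n")
  else for (s in x$selected)
    cat(sprintf("  selected: %s on %s (%s), beta = %.4g\n",
                s$covariate, s$parameter, s$form, s$beta))
  cat(sprintf("  %d candidate fits logged\n", nrow(x$trace)))
  invisible(x)
}

#' Write a covariate-search trace as CSV
#'
#' @param x a `covsearch` or `covsearch_trace` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_search_trace <- function(x, path) {
  write.csv(x$trace, path, row.names = FALSE)
  invisible(path)
}
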