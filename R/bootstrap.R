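# Nonparametric case-resampling bootstrap: whole subjects resampled with
# replacement at the original cohort size, each replicate refitted from the
# base-model optimum; percentile confidence intervals over converged
# replicates only.

#' Nonparametric bootstrap of a population PK fit
#'
#' Each replicate resamples subjects with replacement (a subject drawn
#' twice enters as two independent subjects under fresh ids), refits the
#' model starting from the base-fit optimum, and stores the parameter
#' estimates. Replicates that terminate early (optimizer non-convergence,
#' non-finite OFV, or a variance collapsing to the boundary) are counted
#' and excluded from the percentile summaries.
#'
#' @param fit a converged [poppk()] fit.
#' @param n_reps number of replicates (1000 in the emulated analysis).
#' @param seed integer seed; the full resampling plan is drawn up front so
#'   results are reproducible bit-for-bit.
#' @param stratify_by optional subject-level covariate name (e.g. `"PROT"`);
#'   resampling is then done within each stratum, preserving stratum sizes.
#' @param ci confidence level of the percentile interval (default 0.90:
#'   5th-95th percentiles).
#' @param control fitting control for replicate fits.
#' @return object of class `poppk_boot`: `estimates` (replicate x parameter
#'   matrix, converged replicates), `summary` (median, percentile bounds,
#'   bootstrap \%RSE per parameter), `n_requested`, `n_converged`,
#'   `failures` (reasons), `seed`, `plan` (the subject-resampling index
#'   matrix), `unreliable` (flagged when more than half the replicates
#'   fail).
#' @export
poppk_bootstrap <- function(fit, n_reps = 1000L, seed = NULL,
                            stratify_by = NULL, ci = 0.90,
                            control = poppk_control(se = FALSE)) {
  stopifnot(inherits(fit, "poppk"), n_reps >= 1)
  data <- fit$data
  n <- length(data$subjects)
  plan <- with_seed(seed, {
    if (is.null(stratify_by)) {
      matrix(sample.int(n, n * n_reps, replace = TRUE), nrow = n)
    } else {
      strat <- data$covariates[[stratify_by]]
      if (is.null(strat)) stop_invalid("stratification variable not in data: ", stratify_by)
      m <- matrix(0L, nrow = n, ncol = n_reps)
      for (lev in unique(strat)) {
        idx <- which(strat == lev)
        m[idx, ] <- matrix(idx[sample.int(length(idx), length(idx) * n_reps,
                                          replace = TRUE)], nrow = length(idx))
      }
      m
    }
  })
  q0 <- natural_params(fit$model, fit$est_o)
  est <- matrix(NA_real_, n_reps, length(q0), dimnames = list(NULL, names(q0)))
  reasons <- character(n_reps)
  for (r in seq_len(n_reps)) {
    idx <- plan[, r]
    rd <- resample_data(data, idx)
    rf <- tryCatch(poppk(rd, model = fit$model, method = fit$method,
                         control = control),
                   error = function(e) NULL)
    if (is.null(rf)) { reasons[r] <- "error"; next }
    if (!rf$converged) { reasons[r] <- "non-convergence"; next }
    qr <- natural_params(rf$model, rf$est_o)
    if (any(!is.finite(qr))) { reasons[r] <- "non-finite estimate"; next }
    if (any(qr[grep("^omega2|^sigma2", names(qr))] < 1e-4)) {
      reasons[r] <- "boundary variance"; next
    }
    est[r, ] <- qr[colnames(est)]
    reasons[r] <- ""
  }
  ok <- reasons == ""
  conv <- est[ok, , drop = FALSE]
  a <- (1 - ci) / 2
  summ <- data.frame(
    parameter = colnames(est),
    median = apply(conv, 2, median),
    lower = apply(conv, 2, quantile, probs = a, names = FALSE),
    upper = apply(conv, 2, quantile, probs = 1 - a, names = FALSE),
    rse_percent = 100 * apply(conv, 2, sd) / abs(apply(conv, 2, median))
  )
  rownames(summ) <- NULL
  structure(list(estimates = conv, summary = summ,
                 n_requested = n_reps, n_converged = sum(ok),
                 failures = table(reasons[!ok]), seed = seed, ci = ci,
                 plan = plan, unreliable = sum(!ok) > n_reps / 2),
            class = "poppk_boot")
}

resample_data <- function(data, idx) {
  subjects <- data$subjects[idx]
  for (j in seq_along(subjects)) subjects[[j]]$id <- j   # fresh ids
  structure(list(subjects = subjects,
                 covariates = data$covariates[idx, , drop = FALSE],
                 ids = seq_along(idx), events = NULL),
            class = "poppk_data")
}

#' @export
print.poppk_boot <- function(x, ...) {
  cat(sprintf("Nonparametric bootstrap: %d/%d replicates converged%s\n",
              x$n_converged, x$n_requested,
              if (x$unreliable) " [UNRELIABLE: >50% failures]" else ""))
  if (x$n_requested > x$n_converged)
    cat("  failures:", paste(sprintf("%s (%d)", names(x$failures), x$failures),
                             collapse = ", "), "\n")
  print(format(x$summary, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Write bootstrap replicate estimates as CSV
#'
#' @param x a `poppk_boot` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bootstrap <- function(x, path) {
  write.csv(as.data.frame(x$estimates), path, row.names = FALSE)
  invisible(path)
}
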