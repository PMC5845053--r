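# S3 methods for fitted population PK models

#' @export
print.poppk <- function(x, ...) {
  cat(sprintf("Population PK fit (%s): %d-compartment, %s error\n",
              toupper(x$method), x$model$ncomp, x$model$error))
  cat(sprintf("  %d subjects, %d observations, OFV = %.3f, %s\n",
              length(x$data$subjects), n_obs(x$data), x$ofv,
              if (x$converged) "converged" else "NOT converged"))
  cat("  theta:", paste(sprintf("%s=%.3g", names(x$model$theta), x$model$theta),
                        collapse = "  "), "\n")
  invisible(x)
}

#' Parameter table for a population PK fit
#'
#' One row per estimated parameter: estimate, standard error, \%RSE,
#' eta-shrinkage (IIV terms and residual), and the percent-CV value of each
#' variance under both conventions (see [omega2_to_cv()]).
#'
#' @param object a [poppk()] fit.
#' @param ... unused.
#' @return object of class `summary.poppk` containing the table.
#' @export
summary.poppk <- function(object, ...) {
  m <- object$model
  est_o <- object$est_o
  q <- natural_params(m, est_o)
  se <- object$se %||% setNames(rep(NA_real_, length(q)), names(q))
  rse <- object$rse %||% setNames(rep(NA_real_, length(q)), names(q))
  shr <- setNames(rep(NA_real_, length(q)), names(q))
  for (k in est_o) shr[paste0("omega2.", k)] <- object$shrinkage[[k]]
  eps_shr <- epsilon_shrinkage(object)
  shr["sigma2"] <- eps_shr
  cv <- setNames(rep(NA_real_, length(q)), names(q))
  cva <- cv
  for (k in est_o) {
    cv[paste0("omega2.", k)] <- omega2_to_cv(m$omega2[[k]])
    cva[paste0("omega2.", k)] <- omega2_to_cv(m$omega2[[k]], "sqrt")
  }
  cv["sigma2"] <- cva["sigma2"] <- sigma2_to_cv(m$sigma2)
  tab <- data.frame(parameter = names(q), estimate = unname(q),
                    se = unname(se[names(q)]), rse_percent = unname(rse[names(q)]),
                    shrinkage_percent = unname(shr),
                    cv_percent = unname(cv), cv_percent_sqrt = unname(cva))
  structure(list(table = tab, ofv = object$ofv, method = object$method,
                 converged = object$converged,
                 n_subjects = length(object$data$subjects),
                 n_obs = n_obs(object$data)),
            class = "summary.poppk")
}

# epsilon-shrinkage: 100 * (1 - SD(IWRES)), population denominator
epsilon_shrinkage <- function(fit) {
  d <- tryCatch(residual_diagnostics(fit), warning = function(w) suppressWarnings(residual_diagnostics(fit)))
  iw <- d$IWRES[is.finite(d$IWRES)]
  if (!length(iw)) return(NA_real_)
  100 * (1 - sqrt(mean((iw - mean(iw))^2)))
}

#' @export
print.summary.poppk <- function(x, ...) {
  cat(sprintf("Population PK fit (%s): OFV %.3f, %d subjects / %d obs, %s\n\n",
              toupper(x$method), x$ofv, x$n_subjects, x$n_obs,
              if (x$converged) "converged" else "NOT converged"))
  print(format(x$table, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
coef.poppk <- function(object, ...) {
  natural_params(object$model, object$est_o)
}

#' @export
logLik.poppk <- function(object, ...) {
  structure(-object$ofv / 2,
            df = length(natural_params(object$model, object$est_o)),
            class = "logLik")
}

#' Predicted concentrations from a fit
#'
#' @param object a [poppk()] fit.
#' @param newdata optional event table / `poppk_data` to predict for
#'   (population predictions only); defaults to the fitted data.
#' @param type `"population"` (random effects at zero) or `"individual"`
#'   (empirical Bayes modes; fitted data only).
#' @param ... unused.
#' @return data frame `ID`, `TIME`, `pred`.
#' @export
predict.poppk <- function(object, newdata = NULL,
                          type = c("population", "individual"), ...) {
  type <- match.arg(type)
  data <- if (is.null(newdata)) object$data else as_poppk_data(newdata)
  if (type == "individual" && !is.null(newdata))
    stop_invalid("individual predictions are only defined for the fitted data")
  model <- object$model
  pn <- param_names(model$ncomp)
  th <- typical_value_matrix(model, data$covariates)
  pf <- default_predfun(model)
  rows <- lapply(seq_along(data$subjects), function(i) {
    s <- data$subjects[[i]]
    if (length(s$times) == 0) return(NULL)
    p <- setNames(th[i, pn], pn)
    if (type == "individual") p <- individual_params(p, object$eta[i, ])
    data.frame(ID = s$id, TIME = s$times, pred = pf(p, s))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
residuals.poppk <- function(object, type = c("weighted", "individual", "raw"), ...) {
  type <- match.arg(type)
  d <- residual_diagnostics(object)
  switch(type, weighted = d$WRES, individual = d$IWRES, raw = d$DV - d$PRED)
}

#' Simulate observations from a fitted model
#'
#' Draws new random effects per subject and new residual errors per
#' observation under the fitted model, on the same dosing and sampling
#' design as the data. Backbone of the visual predictive check.
#'
#' @param object a [poppk()] fit.
#' @param nsim number of replicate datasets.
#' @param seed integer seed or `NULL`.
#' @param ... unused.
#' @return numeric matrix, one row per fitted observation (order of
#'   [residual_diagnostics()]) and one column per replicate.
#' @export
simulate.poppk <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, simulate_poppk_(object, nsim))
}

simulate_poppk_ <- function(object, nsim) {
  model <- object$model
  pn <- param_names(model$ncomp)
  th <- typical_value_matrix(model, object$data$covariates)
  pf <- default_predfun(model)
  subs <- object$data$subjects
  nobs_i <- vapply(subs, function(s) length(s$times), 1L)
  out <- matrix(NA_real_, sum(nobs_i), nsim)
  sig <- sqrt(model$sigma2)
  prop <- model$error == "proportional"
  for (r in seq_len(nsim)) {
    row <- 1L
    for (i in seq_along(subs)) {
      s <- subs[[i]]
      if (nobs_i[i] == 0) next
      eta <- rnorm(length(pn), 0, sqrt(model$omega2[pn]))
      p <- individual_params(setNames(th[i, pn], pn), setNames(eta, pn))
      f <- pf(p, s)
      eps <- rnorm(nobs_i[i], 0, sig)
      out[row:(row + nobs_i[i] - 1L), r] <- if (prop) f * (1 + eps) else f + eps
      row <- row + nobs_i[i]
    }
  }
  out
}

#' Goodness-of-fit plots for a population PK fit
#'
#' Standard four-panel display: observed vs population and individual
#' predictions, and weighted residuals against population prediction and
#' time.
#'
#' @param x a [poppk()] fit.
#' @param ... graphical arguments passed to [plot()].
#' @return invisibly, the diagnostics table.
#' @export
plot.poppk <- function(x, ...) {
  d <- residual_diagnostics(x)
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  lim <- range(c(d$DV, d$PRED, d$IPRED), na.rm = TRUE)
  plot(d$PRED, d$DV, xlab = "PRED (ng/mL)", ylab = "DV (ng/mL)",
       xlim = lim, ylim = lim, main = "Observed vs population predicted", ...)
  abline(0, 1, lty = 2)
  plot(d$IPRED, d$DV, xlab = "IPRED (ng/mL)", ylab = "DV (ng/mL)",
       xlim = lim, ylim = lim, main = "Observed vs individual predicted", ...)
  abline(0, 1, lty = 2)
  plot(d$PRED, d$WRES, xlab = "PRED (ng/mL)", ylab = "WRES",
       main = "Weighted residuals vs PRED", ...)
  abline(h = 0, lty = 2)
  plot(d$TIME, d$WRES, xlab = "Time (h)", ylab = "WRES",
       main = "Weighted residuals vs time", ...)
  abline(h = 0, lty = 2)
  invisible(d)
}
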