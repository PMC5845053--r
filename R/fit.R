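# NLME estimation: NONMEM-style OFV (-2 * approximate log marginal
# likelihood, 2*pi constants included) by FOCE-with-interaction or Laplace,
# outer optimization in transformed space (log theta, log omega2, log sigma2)
# so positivity holds by construction.

BIG_OFV <- 1e10

#' Fitting control settings
#'
#' @param rel_tol relative convergence tolerance of the outer optimizer.
#' @param iter_max,eval_max outer iteration/evaluation budget.
#' @param inner_tol gradient tolerance of the per-subject empirical-Bayes
#'   (inner) optimization.
#' @param max_inner inner iteration cap.
#' @param se compute standard errors / \%RSE at the optimum (numeric Hessian
#'   of OFV/2); disable for bootstrap replicates and covariate-search
#'   candidate fits.
#' @param trace outer optimizer trace level.
#' @return a list of class `poppk_control`.
#' @export
poppk_control <- function(rel_tol = 1e-8, iter_max = 400, eval_max = 2000,
                          inner_tol = 1e-8, max_inner = 60, se = TRUE,
                          trace = 0) {
  structure(list(rel_tol = rel_tol, iter_max = iter_max, eval_max = eval_max,
                 inner_tol = inner_tol, max_inner = max_inner, se = se,
                 trace = trace), class = "poppk_control")
}

method_code <- function(method) switch(method, foce = 0L, laplace = 1L)

# engine-order (CL, VC, Q, VT) omega2, padded with zeros for ncomp = 1
omega2_engine <- function(model) {
  o <- setNames(numeric(4), c("CL", "VC", "Q", "VT"))
  o[names(model$omega2)] <- model$omega2
  o
}

subjects_for_engine <- function(data) {
  keep <- vapply(data$subjects, function(s) length(s$dv) > 0, TRUE)
  lapply(data$subjects[keep], function(s)
    list(segs = s$segs, times = s$times, dv = s$dv))
}

# parameter packing for the outer optimizer
pack_model <- function(model) {
  est_o <- names(model$omega2)[model$omega2 > 0]
  betas <- vapply(model$covariates, function(s) s$beta, 0)
  p <- c(log(model$theta), log(model$omega2[est_o]), log(model$sigma2), betas)
  names(p) <- c(paste0("ltheta.", names(model$theta)),
                paste0("lomega2.", est_o, recycle0 = TRUE), "lsigma2",
                vapply(model$covariates,
                       function(s) paste0("beta.", s$parameter, ".", s$covariate), ""))
  list(p = p, est_o = est_o)
}

unpack_model <- function(p, model, est_o) {
  np <- length(model$theta)
  model$theta[] <- exp(p[seq_len(np)])
  k <- np
  if (length(est_o)) {
    model$omega2[est_o] <- exp(p[k + seq_along(est_o)])
    k <- k + length(est_o)
  }
  model$sigma2 <- exp(p[k + 1])
  k <- k + 1
  for (j in seq_along(model$covariates)) {
    model$covariates[[j]]$beta <- p[k + j]
  }
  model
}

# natural-scale reported parameter vector (theta, omega2, sigma2, betas)
natural_params <- function(model, est_o) {
  betas <- vapply(model$covariates, function(s) s$beta, 0)
  q <- c(model$theta, model$omega2[est_o], model$sigma2, betas)
  names(q) <- c(paste0("theta.", names(model$theta)),
                paste0("omega2.", est_o, recycle0 = TRUE), "sigma2",
                vapply(model$covariates,
                       function(s) paste0("beta.", s$parameter, ".", s$covariate), ""))
  q
}

set_natural <- function(q, model, est_o) {
  np <- length(model$theta)
  model$theta[] <- q[seq_len(np)]
  k <- np
  if (length(est_o)) { model$omega2[est_o] <- q[k + seq_along(est_o)]; k <- k + length(est_o) }
  model$sigma2 <- q[k + 1]; k <- k + 1
  for (j in seq_along(model$covariates)) model$covariates[[j]]$beta <- q[k + j]
  model
}

ofv_engine <- function(model, cov_df, subj_cpp, method, etas, control) {
  th <- typical_value_matrix(model, cov_df)
  if (is.null(th) || any(model$theta <= 0) || model$sigma2 <= 0)
    return(list(ofv = BIG_OFV, etas = etas, all_ok = FALSE,
                ofv_i = rep(BIG_OFV, length(subj_cpp)), ok = rep(FALSE, length(subj_cpp))))
  cpp_ofv(t(th), omega2_engine(model), model$sigma2,
          model$error == "proportional", model$ncomp, subj_cpp,
          method_code(method), etas,
          inner_tol = control$inner_tol, max_inner = control$max_inner)
}

#' Objective function value of a population model on a dataset
#'
#' Computes -2 times the approximate log marginal likelihood, summed over
#' subjects, with all normalizing constants included; the Laplace value uses
#' the exact Hessian of the per-subject joint at the empirical Bayes mode,
#' the FOCE value linearizes the predictions about that mode with the
#' residual variance evaluated there (the "interaction"). Both reduce to the
#' exact marginal likelihood when the model is linear-Gaussian in the random
#' effects.
#'
#' @param model a [poppk_model()].
#' @param data an `event_table`, `poppk_data`, or CSV path.
#' @param method `"foce"` (FOCE with interaction) or `"laplace"`.
#' @param backend `"cpp"` (production path) or `"r"` (reference
#'   implementation; required when `predfun` is given).
#' @param predfun optional prediction function `function(params, subject)`
#'   returning predictions at `subject$times`, replacing the infusion PK
#'   model; enables oracle tests on analytically tractable sub-models.
#' @param control a [poppk_control()].
#' @return the OFV, with attributes `etas` (empirical Bayes modes, subjects
#'   in columns), `ofv_i` (per-subject contributions) and `ok`.
#' @export
ofv <- function(model, data, method = c("foce", "laplace"),
                backend = c("cpp", "r"), predfun = NULL,
                control = poppk_control()) {
  method <- match.arg(method)
  backend <- if (!is.null(predfun)) "r" else match.arg(backend)
  data <- as_poppk_data(data)
  if (n_obs(data) == 0) stop_invalid("need at least one subject with observations")
  if (backend == "cpp") {
    subj <- subjects_for_engine(data)
    etas <- matrix(0, 4, length(subj))
    res <- ofv_engine(model, data$covariates, subj, method, etas, control)
    out <- res$ofv
    attr(out, "etas") <- res$etas
    attr(out, "ofv_i") <- res$ofv_i
    attr(out, "ok") <- res$ok
    return(out)
  }
  ofv_r(model, data, method, predfun, control)
}

default_predfun <- function(model) {
  force(model)
  function(params, subject) {
    p4 <- c(params[["CL"]], params[["VC"]],
            if (model$ncomp == 2L) params[["Q"]] else 1,
            if (model$ncomp == 2L) params[["VT"]] else 1)
    as.numeric(cpp_profile(p4, model$ncomp, subject$segs, subject$times))
  }
}

#' Per-subject joint -2 log-likelihood (data and random-effect prior)
#'
#' The inner objective minimized over `eta` for empirical Bayes estimation:
#' `-2 [log p(dv | eta) + log p(eta)]` under the model's residual error and
#' independent Gaussian `eta` priors, constants included. Reference R
#' implementation mirroring the compiled engine.
#'
#' @param eta named random-effect vector (full length; entries whose
#'   `omega2` is zero are treated as fixed at their given value with no
#'   prior contribution).
#' @param model a [poppk_model()].
#' @param subject one element of `poppk_data$subjects` (needs `segs`,
#'   `times`, `dv`); `theta_i` overrides the covariate-adjusted typical
#'   values when given.
#' @param theta_i optional named typical-value vector for this subject.
#' @param predfun optional prediction function (see [ofv()]).
#' @return scalar joint -2 log-likelihood; `+Inf`-like large value if the
#'   prediction is non-finite or non-positive under proportional error.
#' @export
subject_joint_neg2ll <- function(eta, model, subject, theta_i = NULL,
                                 predfun = NULL) {
  pn <- param_names(model$ncomp)
  if (is.null(theta_i)) theta_i <- model$theta
  e <- setNames(numeric(length(pn)), pn)
  if (!is.null(names(eta))) e[names(eta)] <- eta else e[seq_along(eta)] <- eta
  params <- individual_params(theta_i[pn], e)
  f <- if (is.null(predfun)) default_predfun(model)(params, subject)
       else predfun(params, subject)
  if (any(!is.finite(f))) return(BIG_OFV)
  prop <- model$error == "proportional"
  if (prop && any(f < 1e-12)) return(BIG_OFV)
  V <- if (prop) model$sigma2 * f^2 else rep(model$sigma2, length(f))
  r <- subject$dv - f
  g <- sum(log(2 * pi) + log(V) + r^2 / V)
  free <- names(model$omega2)[model$omega2 > 1e-12]
  for (k in free)
    g <- g + log(2 * pi) + log(model$omega2[[k]]) + e[[k]]^2 / model$omega2[[k]]
  if (!is.finite(g)) BIG_OFV else g
}

# reference R implementation of the population OFV
ofv_r <- function(model, data, method, predfun = NULL,
                  control = poppk_control()) {
  pn <- param_names(model$ncomp)
  free <- names(model$omega2)[model$omega2 > 1e-12]
  th <- typical_value_matrix(model, data$covariates)
  if (is.null(th)) return(structure(BIG_OFV, ok = FALSE))
  pf <- predfun %||% default_predfun(model)
  total <- 0
  etas <- matrix(0, length(pn), length(data$subjects),
                 dimnames = list(pn, NULL))
  ok <- rep(TRUE, length(data$subjects))
  ofv_i <- numeric(length(data$subjects))
  for (i in seq_along(data$subjects)) {
    s <- data$subjects[[i]]
    if (length(s$dv) == 0) next
    ti <- setNames(th[i, pn], pn)
    g <- function(ef) {
      e <- setNames(numeric(length(pn)), pn); e[free] <- ef
      subject_joint_neg2ll(e, model, s, theta_i = ti, predfun = pf)
    }
    if (length(free) == 0) {
      ofv_i[i] <- g(numeric(0))
    } else {
      opt <- nlminb(numeric(length(free)), g,
                    control = list(rel.tol = 1e-14, abs.tol = 0))
      ehat <- opt$par
      etas[free, i] <- ehat
      d <- length(free)
      if (method == "laplace") {
        H <- optimHess(ehat, g)
        H <- (H + t(H)) / 2
        ev <- determinant(H / 2, logarithm = TRUE)
        if (ev$sign <= 0) { ok[i] <- FALSE; ofv_i[i] <- BIG_OFV }
        else ofv_i[i] <- opt$objective - d * log(2 * pi) + as.numeric(ev$modulus)
      } else {
        e <- setNames(numeric(length(pn)), pn); e[free] <- ehat
        fhat <- pf(individual_params(ti, e), s)
        h <- 1e-5
        A <- matrix(0, length(fhat), d)
        for (k in seq_len(d)) {
          ep <- ehat; em <- ehat; ep[k] <- ep[k] + h; em[k] <- em[k] - h
          e1 <- e; e1[free] <- ep; e2 <- e; e2[free] <- em
          A[, k] <- (pf(individual_params(ti, e1), s) -
                     pf(individual_params(ti, e2), s)) / (2 * h)
        }
        V <- residual_variance(pmax(fhat, 0), model$sigma2, model$error)
        Sy <- A %*% diag(model$omega2[free], d) %*% t(A) + diag(V, length(V))
        res <- s$dv - fhat + A %*% ehat
        ch <- tryCatch(chol(Sy), error = function(e) NULL)
        if (is.null(ch)) { ok[i] <- FALSE; ofv_i[i] <- BIG_OFV }
        else {
          z <- backsolve(ch, res, transpose = TRUE)
          ofv_i[i] <- length(fhat) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2)
        }
      }
    }
    total <- total + ofv_i[i]
  }
  structure(total, etas = etas, ofv_i = ofv_i, ok = ok)
}

#' Fit a population pharmacokinetic model
#'
#' Maximum-likelihood estimation of a hierarchical infusion PK model by
#' minimizing the approximate -2 log marginal likelihood (see [ofv()]).
#' Typical values, inter-individual variances and the residual variance are
#' optimized on the log scale; covariate coefficients unconstrained.
#' Per-subject empirical Bayes modes are warm-started across outer
#' iterations.
#'
#' @param data an `event_table` data frame, `poppk_data` object, or CSV
#'   path (see [read_event_table()]).
#' @param model initial [poppk_model()]; defaults to literature-magnitude
#'   dexmedetomidine typical values with moderate variability.
#' @param method likelihood approximation: `"foce"` (FOCE with interaction,
#'   default) or `"laplace"`.
#' @param control a [poppk_control()].
#' @return an object of class `poppk` with components `model` (at the
#'   optimum), `ofv`, `se`/`rse` (percent), `eta` (empirical Bayes modes,
#'   subjects x parameters), `shrinkage` (percent, per IIV parameter),
#'   `converged`, and bookkeeping fields. Methods: `print`, `summary`,
#'   `coef`, `logLik`, `predict`, `residuals`, `simulate`, `plot`.
#' @examples
#' \donttest{
#' tab <- simulate_cohort(cohort_config(n_subjects = 12), seed = 7)
#' fit <- poppk(tab, control = poppk_control(se = FALSE))
#' fit
#' }
#' @export
poppk <- function(data, model = poppk_model(), method = c("foce", "laplace"),
                  control = poppk_control()) {
  method <- match.arg(method)
  data <- as_poppk_data(data)
  if (n_obs(data) == 0) stop_invalid("need at least one subject with observations")
  keep <- vapply(data$subjects, function(s) length(s$dv) > 0, TRUE)
  if (!all(keep)) {
    warning(sum(!keep), " subject(s) without observations excluded from fit")
    data$subjects <- data$subjects[keep]
    data$covariates <- data$covariates[keep, , drop = FALSE]
    data$ids <- data$ids[keep]
  }
  subj <- subjects_for_engine(data)
  pk <- pack_model(model)
  zero_etas <- matrix(0, 4, length(subj))
  # inner eta optimization always starts from zero so the outer objective is
  # a deterministic function of the parameters (finite-difference gradients
  # in the outer optimizer would otherwise see history-dependent noise)
  obj <- function(p) {
    m <- unpack_model(p, model, pk$est_o)
    ofv_engine(m, data$covariates, subj, method, zero_etas, control)$ofv
  }
  ofv0 <- obj(pk$p)
  nl_ctl <- list(rel.tol = control$rel_tol, iter.max = control$iter_max,
                 eval.max = control$eval_max, trace = control$trace)
  opt <- nlminb(pk$p, obj, control = nl_ctl)
  opt2 <- nlminb(opt$par, obj, control = nl_ctl)   # cheap restart polish
  if (is.finite(opt2$objective) && opt2$objective <= opt$objective) opt <- opt2
  final <- unpack_model(opt$par, model, pk$est_o)
  res <- ofv_engine(final, data$covariates, subj, method, zero_etas, control)
  # the optimizer's internal finite differences can under-resolve the last
  # mile; accept the terminal point if no coordinate probe at a coarser
  # resolution finds a meaningful descent direction
  h <- 1e-4
  descent <- max(0, max(vapply(seq_along(opt$par), function(i) {
    pp <- opt$par; pm <- opt$par
    pp[i] <- pp[i] + h; pm[i] <- pm[i] - h
    opt$objective - min(obj(pp), obj(pm))
  }, 0)))
  converged <- (opt$convergence == 0 || descent < 0.5) && isTRUE(res$all_ok) &&
    is.finite(res$ofv) && res$ofv < BIG_OFV && res$ofv <= ofv0 + 1e-6
  pn <- param_names(model$ncomp)
  eta <- t(res$etas)[, match(pn, c("CL", "VC", "Q", "VT")), drop = FALSE]
  colnames(eta) <- pn
  rownames(eta) <- as.character(data$ids)
  fit <- structure(list(
    model = final, init = unpack_model(pk$p, model, pk$est_o),
    method = method, data = data, ofv = as.numeric(res$ofv),
    eta = eta, converged = converged, est_o = pk$est_o,
    opt = list(convergence = opt$convergence, message = opt$message,
               iterations = opt$iterations, evaluations = opt$evaluations,
               descent = descent),
    control = control, se = NULL, rse = NULL, cov = NULL
  ), class = "poppk")
  fit$shrinkage <- compute_shrinkage(fit)
  if (control$se && converged) {
    se <- tryCatch(fit_se(fit), error = function(e) {
      warning("standard-error computation failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(se)) { fit$se <- se$se; fit$rse <- se$rse; fit$cov <- se$cov }
  }
  fit
}

# numeric Hessian of OFV on the natural reported scale -> SE and %RSE
fit_se <- function(fit) {
  model <- fit$model
  est_o <- fit$est_o
  q0 <- natural_params(model, est_o)
  data <- fit$data
  subj <- subjects_for_engine(data)
  etas0 <- t(fit$eta)
  full <- matrix(0, 4, ncol(etas0))
  full[match(param_names(model$ncomp), c("CL", "VC", "Q", "VT")), ] <- etas0
  fofv <- function(q) {
    m <- set_natural(q, model, est_o)
    ofv_engine(m, data$covariates, subj, fit$method, full, fit$control)$ofv
  }
  np <- length(q0)
  h <- pmax(abs(q0), 1e-3) * 1e-3
  H <- matrix(0, np, np, dimnames = list(names(q0), names(q0)))
  f0 <- fofv(q0)
  fp <- fm <- numeric(np)
  for (i in seq_len(np)) {
    qp <- q0; qm <- q0
    qp[i] <- qp[i] + h[i]; qm[i] <- qm[i] - h[i]
    fp[i] <- fofv(qp); fm[i] <- fofv(qm)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h[i]^2
  }
  for (i in seq_len(np - 1)) for (j in (i + 1):np) {
    qpp <- q0; qpm <- q0; qmp <- q0; qmm <- q0
    qpp[c(i, j)] <- qpp[c(i, j)] + h[c(i, j)]
    qmm[c(i, j)] <- qmm[c(i, j)] - h[c(i, j)]
    qpm[i] <- qpm[i] + h[i]; qpm[j] <- qpm[j] - h[j]
    qmp[i] <- qmp[i] - h[i]; qmp[j] <- qmp[j] + h[j]
    H[i, j] <- H[j, i] <-
      (fofv(qpp) - fofv(qpm) - fofv(qmp) + fofv(qmm)) / (4 * h[i] * h[j])
  }
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    warning("OFV Hessian not positive definite; standard errors reported as missing")
    se <- setNames(rep(NA_real_, np), names(q0))
    return(list(se = se, rse = se, cov = NULL))
  }
  cov <- 2 * solve(H)   # OFV = -2 logL, so Var = inv(Hessian of -logL)
  se <- sqrt(diag(cov))
  rse <- 100 * se / abs(q0)
  list(se = setNames(se, names(q0)), rse = setNames(rse, names(q0)), cov = cov)
}

#' Percent relative standard errors of a fit
#'
#' `100 * SE / estimate` from the inverse Hessian of half the objective
#' function at the optimum, for fixed and random effects on the natural
#' reporting scale (typical values, variances, covariate coefficients).
#'
#' @param fit a converged [poppk()] fit.
#' @return named vector of \%RSE values (missing if the Hessian was not
#'   positive definite).
#' @export
compute_rse <- function(fit) {
  stopifnot(inherits(fit, "poppk"))
  if (!is.null(fit$rse)) return(fit$rse)
  if (!fit$converged) stop_invalid("fit did not converge; no standard errors")
  fit_se(fit)$rse
}

#' Eta-shrinkage of a fit
#'
#' `100 * (1 - SD(eta_hat) / omega)` per IIV parameter, with the SD taken
#' with the population (n) denominator. High shrinkage means the empirical
#' Bayes estimates collapse toward zero and carry little subject-level
#' information.
#'
#' @param fit a [poppk()] fit with empirical Bayes modes.
#' @return named vector of shrinkage percentages; `NA` where `omega2` is 0.
#' @export
compute_shrinkage <- function(fit) {
  stopifnot(inherits(fit, "poppk"))
  o <- fit$model$omega2
  out <- setNames(rep(NA_real_, length(o)), names(o))
  for (k in names(o)) {
    if (o[[k]] <= 1e-12) next
    e <- fit$eta[, k]
    sdn <- sqrt(mean((e - mean(e))^2))
    out[k] <- 100 * (1 - sdn / sqrt(o[[k]]))
  }
  out
}

#' Observation-level goodness-of-fit table
#'
#' Population predictions (`PRED`, random effects at zero), individual
#' predictions (`IPRED`, empirical Bayes modes), and weighted residuals
#' `WRES = (DV - PRED) / (PRED * sigma)` (proportional error; additive
#' error divides by `sigma` alone), plus `IWRES` analogously.
#'
#' @param fit a [poppk()] fit.
#' @return data frame with one row per fitted observation: `ID`, `TIME`,
#'   `DV`, `PRED`, `IPRED`, `WRES`, `IWRES`.
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "poppk"))
  model <- fit$model
  th <- typical_value_matrix(model, fit$data$covariates)
  pn <- param_names(model$ncomp)
  pf <- default_predfun(model)
  sig <- sqrt(model$sigma2)
  prop <- model$error == "proportional"
  rows <- lapply(seq_along(fit$data$subjects), function(i) {
    s <- fit$data$subjects[[i]]
    if (length(s$dv) == 0) return(NULL)
    ti <- setNames(th[i, pn], pn)
    pred <- pf(ti, s)
    ipred <- pf(individual_params(ti, fit$eta[i, ]), s)
    wden <- if (prop) pred * sig else rep(sig, length(pred))
    iden <- if (prop) ipred * sig else rep(sig, length(pred))
    wres <- ifelse(wden > 0, (s$dv - pred) / wden, NA_real_)
    iwres <- ifelse(iden > 0, (s$dv - ipred) / iden, NA_real_)
    data.frame(ID = s$id, TIME = s$times, DV = s$dv, PRED = pred,
               IPRED = ipred, WRES = wres, IWRES = iwres)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyNA(out$WRES))
    warning("zero population prediction at some observations; weighted residuals missing there")
  out
}
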