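#' Population pharmacokinetic model specification
#'
#' Defines the hierarchical model: typical disposition values `theta`,
#' diagonal lognormal inter-individual variances `omega2` (log scale),
#' residual error variance `sigma2`, and optional covariate terms on the
#' typical values. Individual parameters are `P_i = theta_P * exp(eta_P,i)`
#' with `eta_P,i ~ N(0, omega2_P)`; observations follow
#' `DV = C_P * (1 + eps)` (proportional) or `DV = C_P + eps` (additive),
#' `eps ~ N(0, sigma2)`.
#'
#' @param theta named typical values: `CL` (L/h), `VC` (L) and, for the
#'   two-compartment model, `Q` (L/h) and `VT` (L).
#' @param omega2 named inter-individual variances on the log scale; a value
#'   of 0 pins that parameter's random effect at zero. The default initial
#'   value of 0.3 (~59 \%CV) reflects the high between-patient variability
#'   typical of ICU populations; starting variances well below the truth
#'   can steer the outer optimization into a distribution-phase local
#'   optimum.
#' @param sigma2 residual error variance (proportional scale by default).
#' @param ncomp number of disposition compartments, 1 or 2.
#' @param error residual error model, `"proportional"` or `"additive"`.
#' @param covariates list of [covariate_term()] objects.
#' @return object of class `poppk_model`.
#' @examples
#' # final dexmedetomidine estimates from an ICU analgosedation cohort
#' m <- poppk_model(theta = c(CL = 38.5, VC = 27.0, Q = 46.4, VT = 87.6),
#'                  omega2 = cv_to_omega2(c(CL = 63.2, VC = 124, Q = 80.9, VT = 89)),
#'                  sigma2 = cv_to_sigma2(24))
#' @export
poppk_model <- function(theta = c(CL = 39, VC = 30, Q = 40, VT = 90),
                        omega2 = NULL, sigma2 = 0.04, ncomp = 2L,
                        error = c("proportional", "additive"),
                        covariates = list()) {
  error <- match.arg(error)
  ncomp <- as.integer(ncomp)
  if (!ncomp %in% 1:2) stop_invalid("ncomp must be 1 or 2")
  pn <- param_names(ncomp)
  theta <- unlist(theta)[pn]
  if (any(is.na(theta))) stop_invalid("theta must name all of: ", paste(pn, collapse = ", "))
  if (any(theta <= 0)) stop_invalid("theta must be strictly positive")
  if (is.null(omega2)) omega2 <- setNames(rep(0.3, length(pn)), pn)
  o <- setNames(rep(0, length(pn)), pn)
  o[names(unlist(omega2))] <- unlist(omega2)
  if (any(o < 0)) stop_invalid("omega2 must be non-negative")
  if (!is.numeric(sigma2) || sigma2 <= 0) stop_invalid("sigma2 must be > 0")
  covariates <- lapply(covariates, as_covariate_term)
  keys <- vapply(covariates, function(s) paste(s$parameter, s$covariate), "")
  if (anyDuplicated(keys))
    stop_invalid("at most one covariate term per (parameter, covariate) pair")
  bad <- vapply(covariates, function(s) !s$parameter %in% pn, TRUE)
  if (any(bad)) stop_invalid("covariate terms refer to unknown parameters")
  structure(list(theta = theta, omega2 = o, sigma2 = sigma2, ncomp = ncomp,
                 error = error, covariates = covariates),
            class = "poppk_model")
}

#' @export
print.poppk_model <- function(x, ...) {
  cat(sprintf("Population PK model: %d-compartment infusion, %s residual error\n",
              x$ncomp, x$error))
  cat("  theta :", paste(sprintf("%s=%.4g", names(x$theta), x$theta), collapse = "  "), "\n")
  cat("  omega2:", paste(sprintf("%s=%.4g", names(x$omega2), x$omega2), collapse = "  "), "\n")
  cat(sprintf("  sigma2: %.4g (%.1f %%CV)\n", x$sigma2, sigma2_to_cv(x$sigma2)))
  for (s in x$covariates)
    cat(sprintf("  covariate: %s on %s (%s), beta=%.4g, ref=%.4g\n",
                s$covariate, s$parameter, s$form, s$beta, s$ref %||% NA_real_))
  invisible(x)
}

#' Covariate effect on a typical parameter value
#'
#' The typical value for subject `i` is multiplied by
#' `1 + beta * (x - ref)` (linear), `(x / ref) ^ beta` (power), or
#' `1 + beta * x` (indicator, `x` in 0/1).
#'
#' @param parameter structural parameter name (`CL`, `VC`, `Q`, `VT`).
#' @param covariate covariate column name (e.g. `WT`, `AGE`, `SEX`).
#' @param form functional form: `"power"`, `"linear"` or `"indicator"`.
#' @param beta effect coefficient (estimated when the term is in a fitted
#'   model).
#' @param ref reference covariate value for continuous forms; typically the
#'   population median so `theta` keeps its typical-patient meaning.
#' @return object of class `covariate_term`.
#' @examples
#' covariate_term("CL", "WT", "power", beta = 0.75, ref = 75)
#' @export
covariate_term <- function(parameter, covariate,
                           form = c("power", "linear", "indicator"),
                           beta = 0, ref = NULL) {
  form <- match.arg(form)
  if (form != "indicator") {
    if (is.null(ref)) stop_invalid("continuous forms need a reference value")
    if (form == "power" && ref <= 0)
      stop_invalid("power form needs a positive reference value")
  }
  structure(list(parameter = parameter, covariate = covariate, form = form,
                 beta = as.numeric(beta), ref = ref),
            class = "covariate_term")
}

as_covariate_term <- function(x) {
  if (inherits(x, "covariate_term")) return(x)
  do.call(covariate_term, x)
}

#' Individual parameters from typical values and random effects
#'
#' Applies the lognormal inter-individual model `P_i = theta_P * exp(eta_P)`,
#' strictly positive for every real `eta`.
#'
#' @param theta named positive typical values.
#' @param eta named (or positionally matched) random effects.
#' @return named vector of individual parameters.
#' @examples
#' individual_params(c(CL = 38.5, VC = 27), c(CL = log(2), VC = 0))
#' @export
individual_params <- function(theta, eta) {
  theta <- unlist(theta)
  if (any(theta <= 0)) stop_invalid("theta must be strictly positive")
  e <- setNames(rep(0, length(theta)), names(theta))
  if (!is.null(names(eta))) e[names(eta)] <- eta else e[seq_along(eta)] <- eta
  theta * exp(e)
}

#' Residual error variance at a prediction
#'
#' @param pred predicted concentration(s), ng/mL; must be non-negative for
#'   the proportional model.
#' @param sigma2 residual variance parameter.
#' @param error `"proportional"` (`Var = pred^2 * sigma2`) or `"additive"`
#'   (`Var = sigma2`).
#' @return variance of the observed concentration given the prediction.
#' @export
residual_variance <- function(pred, sigma2, error = c("proportional", "additive")) {
  error <- match.arg(error)
  if (error == "additive") return(rep(sigma2, length(pred)))
  if (any(pred < 0)) stop_invalid("pred must be non-negative")
  pred^2 * sigma2
}

#' Coefficient-of-variation conversions
#'
#' The package's declared convention for reporting a lognormal
#' inter-individual variance `omega2` on the percent-CV scale is the exact
#' lognormal CV, `100 * sqrt(exp(omega2) - 1)`. The common first-order
#' approximation `100 * sqrt(omega2)` is available as `convention = "sqrt"`.
#' The proportional residual SD is reported as `100 * sqrt(sigma2)` %CV.
#'
#' @param omega2,sigma2 variance(s) to convert.
#' @param cv percent CV value(s) to convert back.
#' @param convention `"lognormal"` (default) or `"sqrt"`.
#' @return converted value(s).
#' @examples
#' omega2_to_cv(0.336)          # ~63 %CV
#' cv_to_omega2(63.2)
#' sigma2_to_cv(0.0576)         # 24 %CV
#' @export
omega2_to_cv <- function(omega2, convention = c("lognormal", "sqrt")) {
  convention <- match.arg(convention)
  if (convention == "lognormal") 100 * sqrt(exp(omega2) - 1) else 100 * sqrt(omega2)
}

#' @rdname omega2_to_cv
#' @export
cv_to_omega2 <- function(cv, convention = c("lognormal", "sqrt")) {
  convention <- match.arg(convention)
  if (convention == "lognormal") log(1 + (cv / 100)^2) else (cv / 100)^2
}

#' @rdname omega2_to_cv
#' @export
sigma2_to_cv <- function(sigma2) 100 * sqrt(sigma2)

#' @rdname omega2_to_cv
#' @export
cv_to_sigma2 <- function(cv) (cv / 100)^2

# covariate-adjusted typical values, one row per subject (engine order,
# padded to 4 columns). Returns NULL if any multiplier is non-positive.
typical_value_matrix <- function(model, cov_df) {
  pn <- param_names(model$ncomp)
  n <- if (is.null(cov_df)) 1L else nrow(cov_df)
  th <- matrix(rep(model$theta, each = n), nrow = n, dimnames = list(NULL, pn))
  for (s in model$covariates) {
    if (is.null(cov_df) || is.null(cov_df[[s$covariate]]))
      stop_invalid("covariate ", s$covariate, " not present for all subjects")
    x <- cov_df[[s$covariate]]
    if (any(is.na(x)))
      stop_invalid("covariate ", s$covariate, " not present for all subjects")
    fac <- switch(s$form,
      linear    = 1 + s$beta * (x - s$ref),
      power     = { if (any(x <= 0)) return(NULL); (x / s$ref)^s$beta },
      indicator = 1 + s$beta * x)
    if (any(!is.finite(fac)) || any(fac <= 0)) return(NULL)
    th[, s$parameter] <- th[, s$parameter] * fac
  }
  m4 <- matrix(1, nrow = n, ncol = 4,
               dimnames = list(NULL, c("CL", "VC", "Q", "VT")))
  m4[, pn] <- th
  m4
}
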