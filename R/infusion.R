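#' Piecewise-constant infusion schedule
#'
#' Represents a subject's intravenous dosing history as ordered,
#' non-overlapping constant-rate segments. Rates are in micrograms/hour,
#' times in hours relative to the first dose.
#'
#' @param start,end segment start/end times (hours), equal length.
#' @param rate infusion rate during each segment (micrograms/hour).
#' @return an object of class `infusion_schedule`: a matrix with columns
#'   `start`, `end`, `rate`.
#' @examples
#' # 0.8 ug/kg/h for a 75 kg patient for 24 h, then stepped down to 0.5
#' sched <- infusion_schedule(c(0, 24), c(24, 42), 75 * c(0.8, 0.5))
#' total_dose(sched)
#' @export
infusion_schedule <- function(start, end, rate) {
  if (length(start) != length(end) || length(start) != length(rate))
    stop_invalid("start, end and rate must have equal length")
  m <- cbind(start = as.numeric(start), end = as.numeric(end),
             rate = as.numeric(rate))
  if (nrow(m) > 0) {
    if (any(!is.finite(m))) stop_invalid("schedule entries must be finite")
    if (is.unsorted(m[, "start"], strictly = FALSE))
      stop_invalid("segments must be sorted by start time")
    if (any(m[, "end"] <= m[, "start"]))
      stop_invalid("each segment must satisfy end > start")
    if (nrow(m) > 1 && any(m[-1, "start"] < m[-nrow(m), "end"] - 1e-9))
      stop_invalid("segments must not overlap")
    if (any(m[, "rate"] < 0)) stop_invalid("rates must be non-negative")
  }
  structure(m, class = c("infusion_schedule", "matrix"))
}

#' @rdname infusion_schedule
#' @param schedule an `infusion_schedule`.
#' @return `total_dose()`: total administered dose in micrograms.
#' @export
total_dose <- function(schedule) {
  schedule <- as_infusion_schedule(schedule)
  sum(schedule[, "rate"] * (schedule[, "end"] - schedule[, "start"]))
}

as_infusion_schedule <- function(x) {
  if (inherits(x, "infusion_schedule")) return(x)
  x <- as.matrix(x)
  infusion_schedule(x[, 1], x[, 2], x[, 3])
}

#' Two-compartment disposition parameters
#'
#' @param CL systemic clearance (L/h).
#' @param VC central volume of distribution (L).
#' @param Q inter-compartmental clearance (L/h); omit for a one-compartment
#'   model.
#' @param VT peripheral volume of distribution (L).
#' @return named numeric vector of class `disposition_params` with an
#'   `ncomp` attribute.
#' @examples
#' disposition_params(CL = 38.5, VC = 27.0, Q = 46.4, VT = 87.6)
#' @export
disposition_params <- function(CL, VC, Q = NULL, VT = NULL) {
  one <- is.null(Q) && is.null(VT)
  if (!one && (is.null(Q) || is.null(VT)))
    stop_invalid("supply both Q and VT (two-compartment) or neither")
  p <- if (one) c(CL = CL, VC = VC) else c(CL = CL, VC = VC, Q = Q, VT = VT)
  if (any(!is.finite(p)) || any(p <= 0))
    stop_invalid("disposition parameters must be strictly positive")
  structure(p, ncomp = if (one) 1L else 2L, class = "disposition_params")
}

as_disposition_params <- function(x) {
  if (inherits(x, "disposition_params")) return(x)
  x <- unlist(x)
  nm <- names(x)
  if (is.null(nm) || !all(c("CL", "VC") %in% nm))
    stop_invalid("parameters must be named, with at least CL and VC")
  if (all(c("Q", "VT") %in% nm))
    disposition_params(x[["CL"]], x[["VC"]], x[["Q"]], x[["VT"]])
  else
    disposition_params(x[["CL"]], x[["VC"]])
}

check_times <- function(times) {
  if (length(times) == 0) return(numeric(0))
  if (any(!is.finite(times)) || any(times < 0))
    stop_invalid("times must be finite and non-negative")
  if (is.unsorted(times)) stop_invalid("times must be sorted")
  as.numeric(times)
}

param_matrix <- function(params) {
  # 4-vector in engine order (CL, VC, Q, VT); ones pad a one-compartment model
  nc <- attr(params, "ncomp")
  if (nc == 1L) c(params[["CL"]], params[["VC"]], 1, 1)
  else c(params[["CL"]], params[["VC"]], params[["Q"]], params[["VT"]])
}

#' Central-compartment concentrations under an infusion schedule
#'
#' Closed-form solution of the linear two-compartment disposition system
#' (micro-constants k10 = CL/VC, k12 = Q/VC, k21 = Q/VT) with superposition
#' over constant-rate segments; exactly linear in the infusion rates. Both
#' compartments start empty.
#'
#' @param params disposition parameters (see [disposition_params()]).
#' @param schedule an [infusion_schedule()].
#' @param times sorted, non-negative observation times (hours).
#' @return data frame of class `conc_profile` with columns `time` (h) and
#'   `conc` (ng/mL).
#' @examples
#' p <- disposition_params(CL = 38.5, VC = 27.0, Q = 46.4, VT = 87.6)
#' s <- infusion_schedule(0, 48, 35)   # 35 ug/h for 48 h
#' predict_concentrations(p, s, c(0, 1, 4, 8, 24, 48, 49, 54))
#' @export
predict_concentrations <- function(params, schedule, times) {
  params <- as_disposition_params(params)
  schedule <- as_infusion_schedule(schedule)
  times <- check_times(times)
  conc <- cpp_profile(param_matrix(params), attr(params, "ncomp"),
                      unclass(schedule), times)
  structure(data.frame(time = times, conc = as.numeric(conc)),
            class = c("conc_profile", "data.frame"))
}

#' Numerical-integration oracle for the disposition system
#'
#' Integrates the two-compartment infusion ODE system directly with an
#' adaptive stiff solver ([deSolve::lsoda()]), stopping exactly at every
#' segment boundary so rate discontinuities are never straddled by a step.
#' Serves as an independent cross-check of [predict_concentrations()].
#'
#' @inheritParams predict_concentrations
#' @param tol relative integration tolerance (absolute tolerance is
#'   `tol * 1e-2`).
#' @return data frame with columns `time`, `conc` (central, ng/mL),
#'   `conc_peripheral` (ng/mL) and `eliminated` (cumulative eliminated dose,
#'   micrograms; supports mass-balance checks).
#' @export
integrate_ode_oracle <- function(params, schedule, times, tol = 1e-10) {
  if (!is.numeric(tol) || tol <= 0) stop_invalid("tol must be > 0")
  params <- as_disposition_params(params)
  schedule <- as_infusion_schedule(schedule)
  times <- check_times(times)
  nc <- attr(params, "ncomp")
  CL <- params[["CL"]]; VC <- params[["VC"]]
  Q <- if (nc == 2L) params[["Q"]] else 0
  VT <- if (nc == 2L) params[["VT"]] else 1
  deriv <- function(t, y, parms) {
    cp <- y[1]; ct <- y[2]
    dcp <- (parms - CL * cp - Q * cp + Q * ct) / VC
    dct <- Q * (cp - ct) / VT
    list(c(dcp, dct, CL * cp))
  }
  rate_at <- function(t) {
    hit <- schedule[, "start"] <= t & t < schedule[, "end"]
    if (any(hit)) schedule[hit, "rate"][1] else 0
  }
  # integrate each inter-boundary interval separately with its constant rate,
  # so the stepper never straddles a rate discontinuity
  stops <- sort(unique(c(0, times, schedule[, "start"], schedule[, "end"])))
  y <- c(0, 0, 0)
  res <- matrix(0, length(stops), 3)
  for (i in seq_len(length(stops) - 1)) {
    a <- stops[i]; b <- stops[i + 1]
    out <- deSolve::lsoda(y, c(a, b), deriv, parms = rate_at((a + b) / 2),
                          rtol = tol, atol = tol * 1e-2)
    if (attr(out, "istate")[1] < 0)
      stop_invalid("ODE integration failed (istate = ", attr(out, "istate")[1], ")")
    y <- out[nrow(out), -1]
    res[i + 1, ] <- y
  }
  idx <- match(times, stops)
  data.frame(time = times, conc = res[idx, 1],
             conc_peripheral = res[idx, 2], eliminated = res[idx, 3])
}

#' Hybrid (macro) rate constants of the disposition matrix
#'
#' The two eigenvalue magnitudes of the 2x2 disposition rate matrix,
#' governing the distribution and terminal phases. They satisfy
#' `lambda1 + lambda2 = k10 + k12 + k21` and `lambda1 * lambda2 = k10 * k21`.
#'
#' @inheritParams predict_concentrations
#' @return named vector `c(lambda1, lambda2)` in 1/h, `lambda1 >= lambda2 > 0`.
#' @export
hybrid_constants <- function(params) {
  params <- as_disposition_params(params)
  if (attr(params, "ncomp") == 1L) {
    k <- params[["CL"]] / params[["VC"]]
    return(c(lambda1 = k, lambda2 = k))
  }
  l <- cpp_lambdas(param_matrix(params))
  c(lambda1 = l[1], lambda2 = l[2])
}

#' Clearance unit conversion
#'
#' Converts a clearance in L/h to the weight-normalized mL/min/kg scale.
#'
#' @param cl_l_per_h clearance in L/h.
#' @param weight_kg body weight in kg.
#' @return clearance in mL/min/kg.
#' @examples
#' cl_ml_min_kg(38.5, 70)  # ~9.2
#' @export
cl_ml_min_kg <- function(cl_l_per_h, weight_kg) {
  cl_l_per_h * 1000 / 60 / weight_kg
}
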