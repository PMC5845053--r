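# Synthetic ICU dexmedetomidine cohort generator. Emulates the study
# design: continuous weight-scaled infusion without a loading dose, started
# at 0.8-1 ug/kg/h then maintained at 0.4-1.5 ug/kg/h with recorded step
# adjustments, two arterial sampling protocols anchored to infusion start
# and stop, and the hierarchical model's statistical structure (lognormal
# IIV, proportional residual error).

#' Synthetic cohort configuration
#'
#' Defaults reproduce the emulated study's design: 27 subjects (22 on the
#' short sampling protocol A, 5 on the extended protocol B), weight 45-100
#' kg with median 75, age 19-84 y, infusion durations 23.7-102 h with
#' median ~43 h, and the final published model estimates as simulation
#' truth. Weight and age are drawn from truncated normals calibrated to the
#' reported medians and ranges; duration from a truncated lognormal
#' (right-skewed, as durations are); these shapes are declared assumptions,
#' since only medians and ranges are reported.
#'
#' @param n_subjects cohort size.
#' @param n_protocol_b number of subjects on the extended sampling protocol.
#' @param truth generating [poppk_model()]; defaults to the published final
#'   estimates (CL 38.5 L/h, VC 27 L, Q 46.4 L/h, VT 87.6 L; IIV
#'   63.2/124/80.9/89 \%CV on the lognormal convention; proportional error
#'   24 \%CV).
#' @param weight_range,weight_median,weight_sd weight distribution (kg).
#' @param age_range,age_median,age_sd age distribution (years).
#' @param duration_range,duration_median,duration_sdlog infusion duration
#'   distribution (hours; truncated lognormal).
#' @param initial_rate,maintenance_rate infusion-rate ranges in ug/kg/h for
#'   the first segment and for post-adjustment segments.
#' @param max_adjustments each subject gets 0..`max_adjustments` recorded
#'   step rate adjustments (uniformly).
#' @param p_male,p_inotropes category prevalences (17/27 and 21/27 in the
#'   emulated cohort).
#' @param sofa_range,sofa_center,sofa_sd SOFA score distribution (integer,
#'   rounded truncated normal).
#' @param jitter_sd SD (hours) of Gaussian jitter on nominal sampling
#'   times; 0 gives exact nominal offsets.
#' @param lloq assay lower limit of quantification (ng/mL); simulated
#'   observations falling below it are emitted as missing-DV rows, matching
#'   a study design in which no below-LLOQ measurement entered the
#'   analysis (calibration range 0.05-20 ng/mL).
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 27L,
                          n_protocol_b = max(0L, round(n_subjects * 5 / 27)),
                          truth = poppk_model(
                            theta = c(CL = 38.5, VC = 27.0, Q = 46.4, VT = 87.6),
                            omega2 = cv_to_omega2(c(CL = 63.2, VC = 124, Q = 80.9, VT = 89.0)),
                            sigma2 = cv_to_sigma2(24)),
                          weight_range = c(45, 100), weight_median = 75, weight_sd = 13,
                          age_range = c(19, 84), age_median = 59.5, age_sd = 16,
                          duration_range = c(23.7, 102), duration_median = 42.8,
                          duration_sdlog = 0.33,
                          initial_rate = c(0.8, 1.0),
                          maintenance_rate = c(0.4, 1.5),
                          max_adjustments = 3L,
                          p_male = 17 / 27, p_inotropes = 21 / 27,
                          sofa_range = c(5L, 16L), sofa_center = 12, sofa_sd = 2.5,
                          jitter_sd = 0, lloq = 0.05) {
  stopifnot(n_subjects >= 1, n_protocol_b >= 0, n_protocol_b <= n_subjects,
            weight_range[1] < weight_range[2], age_range[1] < age_range[2],
            duration_range[1] < duration_range[2],
            initial_rate[1] <= initial_rate[2],
            maintenance_rate[1] <= maintenance_rate[2], jitter_sd >= 0)
  structure(as.list(environment()), class = "cohort_config")
}

# inverse-CDF truncated normal
rtnorm <- function(n, mean, sd, lo, hi) {
  qnorm(runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd)), mean, sd)
}

rtlnorm <- function(n, meanlog, sdlog, lo, hi) {
  qlnorm(runif(n, plnorm(lo, meanlog, sdlog), plnorm(hi, meanlog, sdlog)),
         meanlog, sdlog)
}

#' Sample subject-level covariates
#'
#' @param config a [cohort_config()].
#' @param n number of subjects (defaults to `config$n_subjects`).
#' @return data frame with columns `WT`, `AGE`, `SEX` (1 = male), `SOFA`,
#'   `INOTR`, `DUR` (infusion duration, h).
#' @export
sample_covariates <- function(config, n = config$n_subjects) {
  data.frame(
    WT = rtnorm(n, config$weight_median, config$weight_sd,
                config$weight_range[1], config$weight_range[2]),
    AGE = rtnorm(n, config$age_median, config$age_sd,
                 config$age_range[1], config$age_range[2]),
    SEX = rbinom(n, 1, config$p_male),
    SOFA = pmin(config$sofa_range[2], pmax(config$sofa_range[1],
                round(rtnorm(n, config$sofa_center, config$sofa_sd,
                             config$sofa_range[1] - 0.49,
                             config$sofa_range[2] + 0.49)))),
    INOTR = rbinom(n, 1, config$p_inotropes),
    DUR = rtlnorm(n, log(config$duration_median), config$duration_sdlog,
                  config$duration_range[1], config$duration_range[2])
  )
}

#' Build a subject's infusion schedule
#'
#' First segment at the initial weight-scaled rate; each recorded step
#' adjustment switches to a new maintenance rate. No loading dose.
#'
#' @param weight body weight (kg).
#' @param duration total infusion duration (h).
#' @param config a [cohort_config()].
#' @return an [infusion_schedule()] with rates in ug/h.
#' @export
build_schedule <- function(weight, duration, config = cohort_config()) {
  n_adj <- sample.int(config$max_adjustments + 1L, 1L) - 1L
  brk <- sort(runif(n_adj, 0.1 * duration, 0.9 * duration))
  start <- c(0, brk)
  end <- c(brk, duration)
  rates <- weight * c(runif(1, config$initial_rate[1], config$initial_rate[2]),
                      runif(n_adj, config$maintenance_rate[1], config$maintenance_rate[2]))
  infusion_schedule(start, end, rates)
}

#' Protocol sampling times
#'
#' Protocol A: pre-dose and 1, 4, 8, 12, 16, 20 h after infusion start,
#' then just before stop and 5, 10, 20, 60 min and 2, 4, 6 h after stop.
#' Protocol B: pre-dose and 2, 8, 24, 32, 48, 56, 72, 80 h after start,
#' then just before stop and 5, 10, 15, 30, 60 min and 2, 4, 6, 12 h after
#' stop. During-infusion nominal times at or beyond the stop are dropped.
#'
#' @param protocol `"A"` or `"B"`.
#' @param duration infusion stop time (h after start).
#' @param jitter_sd optional Gaussian jitter SD (h) applied to every
#'   sampling time except the pre-dose anchor.
#' @return sorted vector of sampling times (h).
#' @export
sampling_times <- function(protocol = c("A", "B"), duration, jitter_sd = 0) {
  protocol <- match.arg(protocol)
  during <- if (protocol == "A") c(0, 1, 4, 8, 12, 16, 20)
            else c(0, 2, 8, 24, 32, 48, 56, 72, 80)
  post <- if (protocol == "A") c(0, 5 / 60, 10 / 60, 20 / 60, 1, 2, 4, 6)
          else c(0, 5 / 60, 10 / 60, 15 / 60, 30 / 60, 1, 2, 4, 6, 12)
  during <- during[during < duration]
  tt <- c(during, duration + post)
  if (length(tt) <= 1)
    warning("infusion stops before the first post-start sample")
  if (jitter_sd > 0) {
    j <- rnorm(length(tt), 0, jitter_sd)
    j[tt == 0] <- 0
    tt <- pmax(0, tt + j)
  }
  sort(tt)
}

#' Simulate a synthetic ICU cohort
#'
#' Draws covariates and dosing schedules, assigns sampling protocols,
#' draws subject random effects `eta ~ N(0, Omega)` and proportional
#' residual errors (truncated at `eps > -0.999` so observed concentrations
#' stay positive), and emits a NONMEM-style event table. Pre-dose samples
#' (true concentration exactly zero) are emitted as missing-DV rows
#' (`MDV = 1`) and excluded from fitting. The latent truth (random effects
#' and noise-free concentrations) is attached as attribute `"truth"` for
#' recovery testing.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed or `NULL`.
#' @return an `event_table` with covariate columns `WT`, `AGE`, `SEX`,
#'   `SOFA`, `INOTR`, `DUR`, `PROT` and attribute `truth`.
#' @examples
#' tab <- simulate_cohort(cohort_config(n_subjects = 5), seed = 1)
#' head(tab)
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL) {
  with_seed(seed, simulate_cohort_(config))
}

simulate_cohort_ <- function(config) {
  n <- config$n_subjects
  model <- config$truth
  pn <- param_names(model$ncomp)
  cov_df <- sample_covariates(config, n)
  cov_df$PROT <- rep(c(0L, 1L), c(n - config$n_protocol_b, config$n_protocol_b))
  th <- typical_value_matrix(model, cov_df)
  if (is.null(th)) stop_invalid("truth covariate effects give non-positive typical values")
  pf <- default_predfun(model)
  rows <- vector("list", n)
  etas <- matrix(0, n, length(pn), dimnames = list(NULL, pn))
  fs <- vector("list", n)
  for (i in seq_len(n)) {
    sched <- build_schedule(cov_df$WT[i], cov_df$DUR[i], config)
    tt <- sampling_times(if (cov_df$PROT[i] == 1L) "B" else "A",
                         cov_df$DUR[i], config$jitter_sd)
    eta <- rnorm(length(pn), 0, sqrt(model$omega2[pn]))
    etas[i, ] <- eta
    p <- individual_params(setNames(th[i, pn], pn), setNames(eta, pn))
    f <- pf(p, list(segs = unclass(sched), times = tt))
    fs[[i]] <- f
    sig <- sqrt(model$sigma2)
    eps <- rnorm(length(f), 0, sig)
    while (any(bad <- eps <= -0.999))  # keep DV positive; study had no BLQ
      eps[bad] <- rnorm(sum(bad), 0, sig)
    dv <- f * (1 + eps)
    mdv <- as.integer(f <= 0 | dv < config$lloq)
    dv[mdv == 1L] <- NA_real_
    dose <- data.frame(ID = i, TIME = c(sched[, "start"], sched[nrow(sched), "end"]),
                       EVID = 1L,
                       AMT = c(sched[, "rate"] * (sched[, "end"] - sched[, "start"]), 0),
                       RATE = c(sched[, "rate"], 0), DV = NA_real_, MDV = 1L)
    obs <- data.frame(ID = i, TIME = tt, EVID = 0L, AMT = NA_real_,
                      RATE = NA_real_, DV = dv, MDV = mdv)
    sub <- rbind(dose, obs)
    sub <- sub[order(sub$TIME, sub$EVID), ]
    sub <- cbind(sub, cov_df[rep(i, nrow(sub)), , drop = FALSE])
    rows[[i]] <- sub
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab <- as_event_table(tab)
  attr(tab, "truth") <- list(model = model, eta = etas, conc = fs,
                             covariates = cov_df)
  tab
}
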