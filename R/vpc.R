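# Prediction-corrected visual predictive check. Observed and simulated
# concentrations are rescaled within time bins by (bin reference population
# prediction) / (own population prediction), which lets heterogeneous
# dosing regimens and infusion lengths be pooled on one display.

#' Simulate replicate datasets for a VPC
#'
#' @param fit a converged [poppk()] fit.
#' @param n_sim number of simulation replicates.
#' @param seed integer seed.
#' @return matrix, observations (in [residual_diagnostics()] order) by
#'   replicates.
#' @export
simulate_replicates <- function(fit, n_sim = 1000L, seed = NULL) {
  stopifnot(inherits(fit, "poppk"))
  simulate(fit, nsim = n_sim, seed = seed)
}

#' Assign observation times to bins
#'
#' @param obs_times observation times (h).
#' @param strategy `"quantile"` (default: equal-count bins from time
#'   quantiles) or `"nominal"` (snap each time to the nearest supplied
#'   nominal time).
#' @param n_bins number of bins for the quantile strategy.
#' @param nominal nominal times for the snapping strategy.
#' @return integer vector of bin indices (1-based, ordered in time) with
#'   attributes `edges` and `ref` (median time per bin).
#' @export
bin_times <- function(obs_times, strategy = c("quantile", "nominal"),
                      n_bins = 10L, nominal = NULL) {
  strategy <- match.arg(strategy)
  if (length(obs_times) < 1) stop_invalid("need at least one observation")
  if (strategy == "nominal") {
    if (is.null(nominal)) stop_invalid("nominal times required")
    nominal <- sort(unique(nominal))
    idx <- vapply(obs_times, function(t) which.min(abs(nominal - t)), 1L)
    used <- sort(unique(idx))
    bins <- match(idx, used)
  } else {
    ut <- sort(unique(obs_times))
    if (n_bins > length(ut)) {
      warning("more bins than distinct times; collapsed to ", length(ut))
      n_bins <- length(ut)
    }
    edges <- unique(quantile(obs_times, probs = seq(0, 1, length.out = n_bins + 1),
                             names = FALSE, type = 7))
    if (length(edges) < 3) {
      bins <- rep(1L, length(obs_times))
    } else {
      edges[1] <- -Inf; edges[length(edges)] <- Inf
      bins <- as.integer(cut(obs_times, edges, labels = FALSE, right = TRUE))
    }
  }
  ref <- vapply(sort(unique(bins)), function(b) median(obs_times[bins == b]), 0)
  structure(bins, ref = ref, n_bins = length(unique(bins)))
}

#' Prediction correction
#'
#' `pcY_ij = Y_ij * (bin reference PRED) / PRED_ij`, applied identically to
#' observed and simulated values. The bin reference is the median (robust
#' default) or mean of the population predictions in the bin.
#'
#' @param values concentrations to correct (vector or matrix with
#'   observations in rows).
#' @param pred population predictions, one per observation.
#' @param bins bin assignment from [bin_times()].
#' @param ref `"median"` or `"mean"` bin reference.
#' @return corrected values, same shape; observations with non-positive
#'   `pred` are set to `NA` with a warning.
#' @export
prediction_correct <- function(values, pred, bins, ref = c("median", "mean")) {
  ref <- match.arg(ref)
  rf <- switch(ref, median = median, mean = mean)
  fac <- rep(NA_real_, length(pred))
  for (b in unique(bins)) {
    sel <- bins == b
    fac[sel] <- rf(pred[sel]) / pred[sel]
  }
  bad <- !is.finite(fac) | pred <= 0
  if (any(bad)) {
    warning(sum(bad), " observation(s) with non-positive population prediction excluded")
    fac[bad] <- NA_real_
  }
  if (is.matrix(values)) values * fac else as.numeric(values) * fac
}

#' Summarize a VPC
#'
#' Per bin: observed percentiles of the (corrected) data and the
#' simulation-based confidence band of each percentile across replicates.
#'
#' @param observed_pc corrected observed values.
#' @param simulated_pc corrected simulated matrix (observations x
#'   replicates).
#' @param bins bin assignment from [bin_times()].
#' @param percentiles percentiles to track (default 10, 50, 90).
#' @param ci simulation confidence level for the bands (default 95).
#' @return data frame: `bin`, `t_ref`, `n_obs`, `statistic`, `observed`,
#'   `sim_median`, `ci_lo`, `ci_hi`, `flag` (bins with fewer than 3
#'   observations are flagged).
#' @export
vpc_summarize <- function(observed_pc, simulated_pc, bins,
                          percentiles = c(10, 50, 90), ci = 95) {
  if (ncol(simulated_pc) < 20)
    warning("fewer than 20 simulation replicates; confidence bands unstable")
  pr <- percentiles / 100
  a <- (1 - ci / 100) / 2
  tref <- attr(bins, "ref")
  out <- list()
  ub <- sort(unique(bins))
  for (k in seq_along(ub)) {
    sel <- bins == ub[k] & !is.na(observed_pc)
    nb <- sum(sel)
    obs_q <- quantile(observed_pc[sel], pr, names = FALSE, na.rm = TRUE)
    sim_q <- apply(simulated_pc[sel, , drop = FALSE], 2, quantile,
                   probs = pr, names = FALSE, na.rm = TRUE)
    if (length(pr) == 1L) sim_q <- matrix(sim_q, nrow = 1)
    for (j in seq_along(pr)) {
      band <- quantile(sim_q[j, ], c(a, 0.5, 1 - a), names = FALSE, na.rm = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        bin = k, t_ref = tref[k], n_obs = nb,
        statistic = sprintf("p%g", percentiles[j]),
        observed = obs_q[j], sim_median = band[2],
        ci_lo = band[1], ci_hi = band[3],
        flag = nb < 3)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Prediction-corrected visual predictive check
#'
#' Simulates replicate datasets under the fitted model on the observed
#' design, bins observations across time, applies prediction correction to
#' observed and simulated values alike (using population predictions from
#' the final fit, random effects at zero), and summarizes the 10th, 50th
#' and 90th percentiles with simulation-based confidence bands.
#'
#' @param fit a converged [poppk()] fit.
#' @param n_sim simulation replicates (1000 in the emulated analysis).
#' @param n_bins number of time bins (quantile-based equal-count).
#' @param seed integer seed.
#' @param percentiles,ci summary percentiles and band confidence level.
#' @param ref bin reference for the correction, `"median"` (default) or
#'   `"mean"`.
#' @param prediction_corrected set `FALSE` for an uncorrected VPC.
#' @param strategy,nominal binning strategy, see [bin_times()].
#' @return object of class `poppk_vpc`: `summary` data frame, binning and
#'   correction metadata, `seed`. Has `plot` and `print` methods.
#' @export
poppk_vpc <- function(fit, n_sim = 1000L, n_bins = 10L, seed = NULL,
                      percentiles = c(10, 50, 90), ci = 95,
                      ref = c("median", "mean"), prediction_corrected = TRUE,
                      strategy = "quantile", nominal = NULL) {
  stopifnot(inherits(fit, "poppk"))
  ref <- match.arg(ref)
  d <- suppressWarnings(residual_diagnostics(fit))
  sims <- simulate_replicates(fit, n_sim, seed)
  bins <- bin_times(d$TIME, strategy, n_bins, nominal)
  if (prediction_corrected) {
    obs <- suppressWarnings(prediction_correct(d$DV, d$PRED, bins, ref))
    sim <- suppressWarnings(prediction_correct(sims, d$PRED, bins, ref))
  } else {
    obs <- d$DV; sim <- sims
  }
  summ <- vpc_summarize(obs, sim, bins, percentiles, ci)
  structure(list(summary = summ, bins = bins, n_sim = n_sim, seed = seed,
                 percentiles = percentiles, ci = ci, ref = ref,
                 prediction_corrected = prediction_corrected),
            class = "poppk_vpc")
}

#' @export
print.poppk_vpc <- function(x, ...) {
  cat(sprintf("%s: %d bins, %d simulation replicates (bin reference: %s)\n",
              if (x$prediction_corrected) "Prediction-corrected VPC" else "VPC",
              attr(x$bins, "n_bins"), x$n_sim, x$ref))
  inside <- with(x$summary, observed >= ci_lo & observed <= ci_hi)
  cat(sprintf("  observed percentiles inside their simulation band: %d/%d\n",
              sum(inside), length(inside)))
  invisible(x)
}

#' @export
plot.poppk_vpc <- function(x, xlab = "Time (h)",
                           ylab = if (x$prediction_corrected)
                             "Prediction-corrected concentration (ng/mL)"
                           else "Concentration (ng/mL)", ...) {
  s <- x$summary
  stats <- unique(s$statistic)
  xs <- sort(unique(s$t_ref))
  ylim <- range(c(s$ci_lo, s$ci_hi, s$observed), na.rm = TRUE)
  plot(NA, xlim = range(xs), ylim = ylim, xlab = xlab, ylab = ylab,
       main = if (x$prediction_corrected) "pcVPC" else "VPC", ...)
  mid <- stats[ceiling(length(stats) / 2)]
  for (st in stats) {
    ss <- s[s$statistic == st, ]
    ss <- ss[order(ss$t_ref), ]
    colr <- if (st == mid) "steelblue" else "grey60"
    polygon(c(ss$t_ref, rev(ss$t_ref)), c(ss$ci_lo, rev(ss$ci_hi)),
            col = adjustcolor(colr, 0.4), border = NA)
    lines(ss$t_ref, ss$observed, type = "b", pch = 16, cex = 0.7,
          lty = if (st == mid) 1 else 2)
  }
  legend("topright", bty = "n",
         legend = c("median band", "outer percentile bands", "observed"),
         fill = c(adjustcolor("steelblue", 0.4), adjustcolor("grey60", 0.4), NA),
         border = NA, lty = c(NA, NA, 1), pch = c(NA, NA, 16))
  invisible(x)
}

#' Write a VPC summary as CSV
#'
#' @param x a `poppk_vpc` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vpc <- function(x, path) {
  write.csv(x$summary, path, row.names = FALSE)
  invisible(path)
}
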