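# prediction-corrected VPC: simulation, binning, correction, summaries

small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tab <- simulate_cohort(cohort_config(n_subjects = 12), seed = 55)
      cache <<- poppk(tab, control = fast_control())
    }
    cache
  }
})

test_that("simulated replicates equal PRED when all variability is removed", {
  fit <- small_fit()
  fit0 <- fit
  fit0$model$omega2[] <- 0
  fit0$model$sigma2 <- 1e-30
  sims <- simulate_replicates(fit0, n_sim = 3, seed = 1)
  d <- residual_diagnostics(fit0)
  for (j in 1:3) expect_equal(sims[, j], d$PRED, tolerance = 1e-6)
  # seed reproducibility
  s1 <- simulate_replicates(fit, 5, seed = 2)
  s2 <- simulate_replicates(fit, 5, seed = 2)
  expect_identical(s1, s2)
})

test_that("replicate means approach the model expectation", {
  fit <- small_fit()
  fit1 <- fit
  fit1$model$omega2[] <- 0      # only residual noise: E[DV] = PRED
  sims <- simulate_replicates(fit1, n_sim = 800, seed = 3)
  d <- residual_diagnostics(fit1)
  keep <- d$PRED > 0.1
  relerr <- abs(rowMeans(sims)[keep] - d$PRED[keep]) / d$PRED[keep]
  expect_lt(median(relerr), 0.02)
})

test_that("time binning assigns every observation exactly once", {
  expect_warning(b0 <- bin_times(rep(3.5, 7)), "collapsed")
  expect_equal(as.integer(b0), rep(1L, 7))
  tt <- rep(1:10, each = 10) + 0.001 * (1:100)
  b <- bin_times(tt, n_bins = 10)
  expect_equal(unname(table(b)), rep(10L, 10), ignore_attr = TRUE)
  expect_false(anyNA(b))
  expect_warning(b2 <- bin_times(c(1, 1, 2), n_bins = 5), "collapsed")
  # nominal snapping recovers protocol design times as bins
  nom <- sampling_times("A", duration = 24)
  obs <- rep(nom, 3) + rnorm(length(nom) * 3, 0, 0.02)
  bn <- bin_times(pmax(obs, 0), strategy = "nominal", nominal = nom)
  expect_equal(attr(bn, "n_bins"), length(nom))
  expect_equal(unname(table(bn)), rep(3L, length(nom)), ignore_attr = TRUE)
})

test_that("prediction correction follows its formula and degenerates to identity", {
  pred <- c(1, 1, 1, 2, 2, 2)
  bins <- structure(c(1L, 1L, 1L, 2L, 2L, 2L), ref = c(1, 2))
  y <- c(0.5, 1, 2, 1, 2, 4)
  expect_equal(prediction_correct(y, pred, bins), y)  # equal PRED within bin
  # a value with PRED twice the bin average is halved: Y=4, PRED=2, avg=1 -> 2
  pred2 <- c(0.5, 1, 2)
  bins2 <- structure(rep(1L, 3), ref = 1)
  out <- prediction_correct(c(1, 1, 4), pred2, bins2, ref = "median")
  expect_equal(out[3], 4 * 1 / 2)
  # correction commutes with percentile ranking when PRED is constant within bin
  set.seed(8)
  yy <- rlnorm(30)
  out2 <- prediction_correct(yy, rep(2, 30), structure(rep(1L, 30), ref = 1))
  expect_identical(order(out2), order(yy))
  expect_warning(prediction_correct(1, 0, structure(1L, ref = 1)), "non-positive")
})

test_that("VPC summaries respect percentile ordering and band structure", {
  fit <- small_fit()
  v <- poppk_vpc(fit, n_sim = 60, n_bins = 6, seed = 10)
  s <- v$summary
  expect_true(all(s$ci_lo <= s$ci_hi))
  for (b in unique(s$bin)) {
    sb <- s[s$bin == b, ]
    expect_true(all(diff(sb$observed[match(c("p10", "p50", "p90"), sb$statistic)]) >= 0))
  }
  # simulated replicates identical to observed: observed sits on the band midline
  d <- suppressWarnings(residual_diagnostics(fit))
  bins <- bin_times(d$TIME, n_bins = 5)
  simmat <- matrix(rep(d$DV, 50), ncol = 50)
  ss <- vpc_summarize(d$DV, simmat, bins)
  expect_equal(ss$observed, ss$sim_median, tolerance = 1e-12)
  expect_equal(ss$observed, ss$ci_lo, tolerance = 1e-12)
  # low-count bins are flagged
  ss2 <- vpc_summarize(d$DV[1:2], simmat[1:2, , drop = FALSE],
                       structure(c(1L, 1L), ref = 1))
  expect_true(all(ss2$flag))
})

test_that("pooled sub-cohorts on different regimens overlay after correction", {
  # two sub-cohorts at very different infusion rates; prediction correction
  # must bring their percentile bands onto a common scale
  cc1 <- cohort_config(n_subjects = 8, initial_rate = c(0.4, 0.5),
                       maintenance_rate = c(0.4, 0.5), max_adjustments = 0L)
  cc2 <- cohort_config(n_subjects = 8, initial_rate = c(1.4, 1.5),
                       maintenance_rate = c(1.4, 1.5), max_adjustments = 0L)
  t1 <- as.data.frame(simulate_cohort(cc1, seed = 61))
  t2 <- as.data.frame(simulate_cohort(cc2, seed = 62))
  t2$ID <- t2$ID + 100
  tab <- as_event_table(rbind(t1, t2))
  fit <- poppk(tab, control = fast_control())
  v <- poppk_vpc(fit, n_sim = 150, n_bins = 6, seed = 63)
  inside <- with(v$summary, observed >= ci_lo & observed <= ci_hi)
  expect_gte(mean(inside), 0.7)
})
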