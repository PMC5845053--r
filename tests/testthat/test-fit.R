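# marginal-likelihood machinery: joint objective, FOCE/Laplace OFV against
# analytic and quadrature oracles, fitting behaviour, diagnostics

test_that("joint -2LL reduces to its normalizing constants at zero residuals", {
  # one subject, additive error, predictions forced equal to the data
  toy <- linear_toy(a = c(1, 2), b = c(0, 0), y = c(1, 2),
                    omega2 = 0.09, sigma2 = 0.25)
  g <- subject_joint_neg2ll(c(CL = 0, VC = 0, Q = 0, VT = 0), toy$model,
                            toy$data$subjects[[1]], predfun = toy$predfun)
  expect_equal(g, 2 * (log(2 * pi) + log(0.25)) + (log(2 * pi) + log(0.09)),
               tolerance = 1e-12)
})

test_that("joint -2LL is quadratic in eta for a model linear in eta", {
  toy <- linear_toy(a = c(1, 0.5), b = c(2, 1), y = c(1.4, 0.9))
  g <- function(e) subject_joint_neg2ll(c(CL = e, VC = 0, Q = 0, VT = 0),
                                        toy$model, toy$data$subjects[[1]],
                                        predfun = toy$predfun)
  # closed-form Gaussian posterior mode and curvature
  b <- c(2, 1); y <- c(1.4, 0.9); a <- c(1, 0.5)
  prec <- sum(b^2) / 0.25 + 1 / 0.09
  mode <- sum(b * (y - a)) / 0.25 / prec
  es <- seq(-2, 2, by = 0.25)
  vals <- vapply(es, g, 0)
  quad <- vapply(es, function(e) g(mode) + prec * (e - mode)^2, 0)
  expect_equal(vals, quad, tolerance = 1e-8)
  # finite at extreme eta
  expect_true(is.finite(g(10)) && is.finite(g(-10)))
})

test_that("Laplace and FOCE equal adaptive quadrature and the closed form on a linear toy", {
  set.seed(2)
  a <- c(0.5, 1, 1.5); b <- c(1, -0.5, 2)
  y <- a + b * 0.2 + rnorm(3, 0, 0.3)
  toy <- linear_toy(a, b, y)
  lap <- as.numeric(ofv(toy$model, toy$data, "laplace", predfun = toy$predfun))
  foc <- as.numeric(ofv(toy$model, toy$data, "foce", predfun = toy$predfun))
  g <- function(e) subject_joint_neg2ll(c(CL = e, VC = 0, Q = 0, VT = 0),
                                        toy$model, toy$data$subjects[[1]],
                                        predfun = toy$predfun)
  agq <- agq_neg2ll(g, 41)
  expect_equal(lap, toy$exact, tolerance = 1e-6)
  expect_equal(foc, toy$exact, tolerance = 1e-6)
  expect_equal(agq, toy$exact, tolerance = 1e-6)
})

test_that("Laplace OFV tracks direct numerical integration on a nonlinear PK toy", {
  set.seed(1)
  m <- poppk_model(theta = c(CL = 38.5, VC = 27, Q = 46.4, VT = 87.6),
                   omega2 = c(CL = 0.3, VC = 0, Q = 0, VT = 0), sigma2 = 0.0576)
  sched <- infusion_schedule(0, 30, 60)
  tt <- c(1, 4, 8, 12, 24, 30.2, 31, 34)
  f <- predict_concentrations(c(CL = 38.5 * exp(0.4), VC = 27, Q = 46.4, VT = 87.6),
                              sched, tt)$conc
  dv <- f * (1 + rnorm(8, 0, 0.24))
  subject <- list(id = 1, segs = cbind(0, 30, 60), times = tt, dv = dv,
                  covariates = list())
  data <- structure(list(subjects = list(subject),
                         covariates = data.frame(row.names = 1), ids = 1,
                         events = NULL), class = "poppk_data")
  lik <- function(eta) vapply(eta, function(e) {
    p <- c(CL = 38.5 * exp(e), VC = 27, Q = 46.4, VT = 87.6)
    fp <- predict_concentrations(p, sched, tt)$conc
    prod(dnorm(dv, fp, fp * 0.24)) * dnorm(e, 0, sqrt(0.3))
  }, 0)
  exact <- -2 * log(integrate(lik, -6, 6, rel.tol = 1e-12)$value)
  lap_cpp <- as.numeric(ofv(m, data, "laplace", backend = "cpp"))
  lap_r <- as.numeric(ofv(m, data, "laplace", backend = "r"))
  expect_equal(lap_cpp, lap_r, tolerance = 1e-5)
  expect_equal(lap_cpp, exact, tolerance = 0.1)   # Laplace approximation error
})

test_that("compiled and reference OFV backends agree on a simulated cohort", {
  tab <- simulate_cohort(cohort_config(n_subjects = 5), seed = 42)
  m <- table2_model()
  for (meth in c("foce", "laplace")) {
    oc <- as.numeric(ofv(m, tab, meth, backend = "cpp"))
    or <- as.numeric(ofv(m, tab, meth, backend = "r"))
    expect_equal(oc, or, tolerance = 1e-4)
  }
})

test_that("OFV is invariant to subject order and collapses correctly as omega -> 0", {
  tab <- simulate_cohort(cohort_config(n_subjects = 6), seed = 9)
  m <- table2_model()
  d <- as_poppk_data(tab)
  o1 <- as.numeric(ofv(m, d, "foce"))
  perm <- rev(seq_along(d$subjects))
  d2 <- d
  d2$subjects <- d$subjects[perm]
  d2$covariates <- d$covariates[perm, , drop = FALSE]
  d2$ids <- d$ids[perm]
  expect_equal(as.numeric(ofv(m, d2, "foce")), o1, tolerance = 1e-12)
  # omega2 = 0 pins eta at zero: OFV equals the fixed-effects -2LL
  m0 <- poppk_model(theta = m$theta, omega2 = c(CL = 0, VC = 0, Q = 0, VT = 0),
                    sigma2 = m$sigma2)
  o0 <- as.numeric(ofv(m0, d, "foce"))
  direct <- 0
  for (s in d$subjects) {
    f <- predict_concentrations(m$theta, infusion_schedule(s$segs[, 1], s$segs[, 2], s$segs[, 3]),
                                s$times)$conc
    V <- f^2 * m$sigma2
    direct <- direct + sum(log(2 * pi * V) + (s$dv - f)^2 / V)
  }
  expect_equal(o0, direct, tolerance = 1e-8)
  expect_equal(as.numeric(ofv(m0, d, "laplace")), direct, tolerance = 1e-8)
})

test_that("noise-free data with no IIV is recovered to optimizer tolerance", {
  cc <- cohort_config(n_subjects = 8)
  cc$truth$omega2[] <- 0
  cc$truth$sigma2 <- 1e-6   # generator needs sigma2 > 0; effectively noise-free
  tab <- suppressWarnings(simulate_cohort(cc, seed = 4))
  init <- poppk_model(theta = c(CL = 30, VC = 20, Q = 30, VT = 60),
                      omega2 = c(CL = 0, VC = 0, Q = 0, VT = 0), sigma2 = 0.01)
  fit <- poppk(tab, model = init, control = fast_control())
  expect_equal(unname(fit$model$theta), c(38.5, 27.0, 46.4, 87.6),
               tolerance = 1e-3)
})

test_that("refitting from the optimum does not change the OFV materially", {
  tab <- simulate_cohort(cohort_config(n_subjects = 10), seed = 15)
  fit <- poppk(tab, control = fast_control())
  fit2 <- poppk(tab, model = fit$model, control = fast_control())
  expect_lte(fit2$ofv, fit$ofv + 1e-4)
  expect_gt(fit2$ofv, fit$ofv - 0.5)
})

test_that("shrinkage follows its definition in the degenerate cases", {
  fit <- structure(list(model = poppk_model(omega2 = c(CL = 0.25, VC = 0.25, Q = 0, VT = 0.25)),
                        eta = NULL), class = "poppk")
  set.seed(3)
  n <- 4000
  eta <- cbind(CL = rnorm(n, 0, 0.5), VC = rep(0, n), Q = rep(0, n),
               VT = rnorm(n, 0, 0.25))
  fit$eta <- eta
  shr <- compute_shrinkage(fit)
  expect_lt(abs(shr[["CL"]]), 3)                      # eta drawn at the prior SD
  expect_equal(shr[["VC"]], 100)                      # all EBEs collapsed
  expect_true(is.na(shr[["Q"]]))                      # omega2 = 0: undefined
  expect_lt(abs(shr[["VT"]] - 50), 3)                 # half the prior SD
})

test_that("standard errors shrink about 1/sqrt(2) when the dataset is duplicated", {
  tab <- simulate_cohort(cohort_config(n_subjects = 14), seed = 31)
  fit1 <- poppk(tab)
  tab2 <- as.data.frame(tab)
  dup <- tab2
  dup$ID <- dup$ID + 1000
  both <- as_event_table(rbind(tab2, dup))
  fit2 <- poppk(both, model = fit1$model)
  expect_true(all(fit1$rse >= 0, na.rm = TRUE))
  ratio <- fit2$rse / fit1$rse
  expect_equal(median(ratio, na.rm = TRUE), 1 / sqrt(2), tolerance = 0.15)
})

test_that("residual diagnostics satisfy their structural properties", {
  tab <- simulate_cohort(cohort_config(n_subjects = 12), seed = 8)
  fit <- poppk(tab, control = fast_control())
  d <- residual_diagnostics(fit)
  expect_equal(nrow(d), sum(tab$EVID == 0 & tab$MDV == 0))
  # noise-free self-fit: predictions at the latent truth reproduce the data
  cc <- cohort_config(n_subjects = 4)
  cc$truth$omega2[] <- 0
  cc$truth$sigma2 <- 1e-12
  tab0 <- simulate_cohort(cc, seed = 5)
  init <- cc$truth
  fit0 <- structure(list(model = init, data = as_poppk_data(tab0),
                         eta = matrix(0, 4, 4, dimnames = list(NULL, c("CL", "VC", "Q", "VT"))),
                         est_o = character(0)), class = "poppk")
  d0 <- residual_diagnostics(fit0)
  expect_equal(d0$IPRED, d0$DV, tolerance = 1e-5)
  # weighted residuals approximately standard normal on a well-specified fit
  tabw <- simulate_cohort(cohort_config(n_subjects = 40), seed = 77)
  fitw <- poppk(tabw, control = fast_control())
  dw <- residual_diagnostics(fitw)
  expect_gt(nrow(dw), 500)
  expect_lt(abs(mean(dw$IWRES)), 0.1)
})

test_that("the Laplace method also fits a cohort end to end", {
  tab <- simulate_cohort(cohort_config(n_subjects = 20), seed = 24)
  fit <- poppk(tab, method = "laplace", control = fast_control())
  expect_true(fit$converged)
  expect_equal(unname(fit$model$theta[["CL"]]), 38.5, tolerance = 0.4)
})

test_that("a one-compartment reduction can be fitted for model comparison", {
  tab <- simulate_cohort(cohort_config(n_subjects = 10), seed = 19)
  fit1 <- poppk(tab, model = one_comp_init(), control = fast_control())
  fit2 <- poppk(tab, control = fast_control())
  expect_true(fit1$converged)
  # the generating model is two-compartment: the fuller model fits better
  expect_lt(fit2$ofv, fit1$ofv)
})
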