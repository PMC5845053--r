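# shared fixtures and oracles, all built in code

table2_model <- function() {
  poppk_model(theta = c(CL = 38.5, VC = 27.0, Q = 46.4, VT = 87.6),
              omega2 = cv_to_omega2(c(CL = 63.2, VC = 124, Q = 80.9, VT = 89.0)),
              sigma2 = cv_to_sigma2(24))
}

random_disposition <- function() {
  disposition_params(CL = exp(runif(1, log(5), log(80))),
                     VC = exp(runif(1, log(5), log(80))),
                     Q = exp(runif(1, log(5), log(100))),
                     VT = exp(runif(1, log(20), log(300))))
}

random_schedule <- function() {
  k <- sample(1:4, 1)
  brk <- sort(runif(k + 1, 0, 60))
  infusion_schedule(brk[-(k + 1)], brk[-1], runif(k, 0, 120))
}

# small one-compartment null cohort (constant infusion, sparse sampling);
# used for covariate-search calibration at a scale where many refits are fast
one_comp_cohort <- function(n = 20, beta_wt = 0, seed = NULL,
                            omega2 = c(0.2, 0.2)) {
  gen <- function() {
    wt <- runif(n, 45, 100)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      eta <- rnorm(2, 0, sqrt(omega2))
      cl <- 39 * (wt[i] / 75)^beta_wt * exp(eta[1])
      p <- c(CL = cl, VC = 40 * exp(eta[2]))
      sch <- infusion_schedule(0, 24, 50)
      tt <- c(2, 6, 12, 23, 24.5, 26)
      f <- predict_concentrations(p, sch, tt)$conc
      dv <- f * (1 + rnorm(length(f), 0, 0.2))
      sub <- rbind(
        data.frame(ID = i, TIME = c(0, 24), EVID = 1L, AMT = c(1200, 0),
                   RATE = c(50, 0), DV = NA_real_, MDV = 1L, WT = wt[i]),
        data.frame(ID = i, TIME = tt, EVID = 0L, AMT = NA_real_,
                   RATE = NA_real_, DV = dv, MDV = 0L, WT = wt[i]))
      rows[[i]] <- sub[order(sub$TIME, sub$EVID), ]
    }
    as_event_table(do.call(rbind, rows))
  }
  if (is.null(seed)) gen() else dexpoppk:::with_seed(seed, gen())
}

one_comp_init <- function() {
  poppk_model(theta = c(CL = 35, VC = 35), omega2 = c(CL = 0.15, VC = 0.15),
              sigma2 = 0.05, ncomp = 1)
}

fast_control <- function() poppk_control(se = FALSE)

# linear-Gaussian toy: additive error, predictions linear in eta through the
# log of the lognormal individual parameter (f = a + b * log(P/theta) = a + b*eta);
# the marginal likelihood is available in closed form
linear_toy <- function(a, b, y, omega2 = 0.09, sigma2 = 0.25) {
  model <- poppk_model(theta = c(CL = 38.5, VC = 27, Q = 46.4, VT = 87.6),
                       omega2 = c(CL = omega2, VC = 0, Q = 0, VT = 0),
                       sigma2 = sigma2, error = "additive")
  predfun <- function(params, subject) a + b * log(params[["CL"]] / 38.5)
  subject <- list(id = 1, segs = cbind(0, 1, 0), times = seq_along(y), dv = y,
                  covariates = list())
  data <- structure(list(subjects = list(subject),
                         covariates = data.frame(row.names = 1),
                         ids = 1, events = NULL), class = "poppk_data")
  neg2ll_exact <- {
    S <- outer(b, b) * omega2 + diag(sigma2, length(y))
    r <- y - a
    length(y) * log(2 * pi) + as.numeric(determinant(S)$modulus) +
      drop(r %*% solve(S, r))
  }
  list(model = model, predfun = predfun, data = data, exact = neg2ll_exact)
}

# adaptive Gauss-Hermite oracle for a one-dimensional random effect:
# -2 log integral of exp(-joint_neg2ll(eta)/2) d eta
agq_neg2ll <- function(g, n_nodes = 41) {
  gh <- pracma::gaussHermite(n_nodes)
  opt <- optimize(g, c(-10, 10), tol = 1e-12)
  m <- opt$minimum
  h <- 1e-4
  curv <- (g(m + h) - 2 * g(m) + g(m - h)) / h^2   # of g = -2 log joint
  s <- 1 / sqrt(pmax(curv / 2, 1e-12))
  z <- m + sqrt(2) * s * gh$x
  vals <- vapply(z, g, 0)
  # stabilized log-sum-exp of w_i exp(x_i^2) exp(-g/2) * sqrt(2) s
  le <- log(gh$w) + gh$x^2 - vals / 2
  M <- max(le)
  -2 * (M + log(sum(exp(le - M))) + 0.5 * log(2) + log(s))
}
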