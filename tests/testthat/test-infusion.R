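# closed-form two-compartment disposition vs independent oracles

test_that("schedule and parameter validation reject invalid input", {
  expect_error(infusion_schedule(c(0, 1), c(2, 3), c(5, 5)), "overlap")
  expect_error(infusion_schedule(1, 1, 5), "end > start")
  expect_error(infusion_schedule(0, 2, -1), "non-negative")
  expect_error(infusion_schedule(c(2, 0), c(3, 1), c(1, 1)), "sorted")
  expect_error(disposition_params(CL = -1, VC = 10, Q = 1, VT = 1), "positive")
  expect_error(disposition_params(CL = 1, VC = 10, Q = 1), "both Q and VT")
  p <- disposition_params(CL = 38.5, VC = 27, Q = 46.4, VT = 87.6)
  expect_error(predict_concentrations(p, infusion_schedule(0, 1, 10), c(2, 1)), "sorted")
  expect_error(predict_concentrations(p, infusion_schedule(0, 1, 10), -1), "non-negative")
  expect_error(integrate_ode_oracle(p, infusion_schedule(0, 1, 10), 1, tol = 0), "tol")
})

test_that("concentration is zero before dosing and R/CL at steady state", {
  p <- disposition_params(CL = 38.5, VC = 27, Q = 46.4, VT = 87.6)
  s <- infusion_schedule(5, 10, 70)
  expect_equal(predict_concentrations(p, s, c(0, 1, 4.99))$conc, rep(0, 3))
  # constant infusion to effective steady state: C_ss = R / CL
  long <- infusion_schedule(0, 3000, 35)
  expect_equal(predict_concentrations(p, long, 3000)$conc, 35 / 38.5,
               tolerance = 1e-9)
  # zero-rate schedule stays identically zero in both implementations
  z <- infusion_schedule(0, 10, 0)
  expect_equal(predict_concentrations(p, z, c(0, 5, 10))$conc, rep(0, 3))
  expect_equal(integrate_ode_oracle(p, z, c(0, 5, 10))$conc, rep(0, 3))
})

test_that("closed form matches the stiff ODE oracle on randomized cases", {
  set.seed(101)
  worst <- 0
  for (k in 1:100) {
    p <- random_disposition()
    s <- random_schedule()
    tt <- sort(c(runif(8, 0, 80), s[, "end"]))
    cf <- predict_concentrations(p, s, tt)$conc
    od <- integrate_ode_oracle(p, s, tt, tol = 1e-12)$conc
    # relative comparison down to 1e-4 of the peak; deeper washout values sit
    # below the integrator's own accumulated-error floor and are compared on
    # that absolute scale instead
    scale <- pmax(abs(od), 1e-4 * max(od))
    worst <- max(worst, max(abs(cf - od) / scale))
  }
  expect_lt(worst, 1e-8)
})

test_that("superposition and exact dose proportionality hold", {
  set.seed(7)
  for (k in 1:20) {
    p <- random_disposition()
    a <- random_schedule()
    b <- random_schedule()
    tt <- sort(runif(12, 0, 90))
    ca <- predict_concentrations(p, a, tt)$conc
    cb <- predict_concentrations(p, b, tt)$conc
    # merge A and B into one valid schedule by summing rates over the
    # union of breakpoints, then compare against the sum of profiles
    brk <- sort(unique(c(a[, 1:2], b[, 1:2])))
    rate_at <- function(s, t) {
      hit <- s[, "start"] <= t & t < s[, "end"]
      if (any(hit)) sum(s[hit, "rate"]) else 0
    }
    mid <- head(brk, -1) + diff(brk) / 2
    comb <- infusion_schedule(head(brk, -1), brk[-1],
                              vapply(mid, function(t) rate_at(a, t) + rate_at(b, t), 0))
    cab <- predict_concentrations(p, comb, tt)$conc
    expect_equal(cab, ca + cb, tolerance = 1e-10)
    doubled <- infusion_schedule(a[, "start"], a[, "end"], 2 * a[, "rate"])
    expect_equal(predict_concentrations(p, doubled, tt)$conc, 2 * ca,
                 tolerance = 1e-12)
  }
})

test_that("mass balance holds along the ODE oracle", {
  set.seed(11)
  for (k in 1:10) {
    p <- random_disposition()
    s <- random_schedule()
    tt <- sort(c(runif(5, 0, 70), max(s[, "end"]) + 5))
    od <- integrate_ode_oracle(p, s, tt, tol = 1e-12)
    dosed <- vapply(tt, function(t) {
      dur <- pmin(t, s[, "end"]) - pmin(t, s[, "start"])
      sum(s[, "rate"] * dur)
    }, 0)
    held <- p[["VC"]] * od$conc + p[["VT"]] * od$conc_peripheral + od$eliminated
    expect_equal(held, dosed, tolerance = 1e-7)
  }
})

test_that("concentration decreases strictly during washout", {
  set.seed(13)
  for (k in 1:10) {
    p <- random_disposition()
    s <- random_schedule()
    t_end <- max(s[, "end"])
    tt <- t_end + seq(0.5, 40, by = 0.5)
    conc <- predict_concentrations(p, s, tt)$conc
    expect_true(all(diff(conc) < 0))
  }
})

test_that("concentration is continuous across segment boundaries", {
  p <- disposition_params(CL = 38.5, VC = 27, Q = 46.4, VT = 87.6)
  s <- infusion_schedule(c(0, 24), c(24, 42), c(60, 40))
  eps <- 1e-9
  for (tb in c(24, 42)) {
    c3 <- predict_concentrations(p, s, c(tb - eps, tb, tb + eps))$conc
    expect_equal(c3[2], c3[1], tolerance = 1e-6)
    expect_equal(c3[2], c3[3], tolerance = 1e-6)
  }
})

test_that("hybrid rate constants satisfy the eigenvalue identities", {
  # published typical values, cross-checked against a direct eigen solve
  p <- disposition_params(CL = 38.5, VC = 27, Q = 46.4, VT = 87.6)
  l <- hybrid_constants(p)
  A <- matrix(c(-(38.5 + 46.4) / 27, 46.4 / 87.6, 46.4 / 27, -46.4 / 87.6), 2)
  ev <- sort(abs(eigen(A, only.values = TRUE)$values), decreasing = TRUE)
  expect_equal(unname(l), ev, tolerance = 1e-12)
  set.seed(17)
  for (k in 1:50) {
    q <- random_disposition()
    l <- hybrid_constants(q)
    k10 <- q[["CL"]] / q[["VC"]]; k12 <- q[["Q"]] / q[["VC"]]; k21 <- q[["Q"]] / q[["VT"]]
    expect_equal(unname(l[1] * l[2]), k10 * k21, tolerance = 1e-12)
    expect_equal(unname(l[1] + l[2]), k10 + k12 + k21, tolerance = 1e-12)
  }
  # one-compartment reduction: Q -> 0 gives {CL/VC, Q/VT}
  q0 <- disposition_params(CL = 38.5, VC = 27, Q = 1e-7, VT = 87.6)
  l0 <- hybrid_constants(q0)
  expect_equal(unname(l0[1]), 38.5 / 27, tolerance = 1e-6)
  expect_equal(unname(l0[2]), 1e-7 / 87.6, tolerance = 1e-4)
})

test_that("clearance unit conversion matches direct arithmetic", {
  expect_equal(cl_ml_min_kg(38.5, 70), 38.5 * 1000 / 60 / 70)
})
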