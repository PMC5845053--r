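# hierarchical model components: lognormal IIV, proportional error,
# CV conventions, covariate forms

test_that("lognormal individual parameters behave as specified", {
  th <- c(CL = 38.5, VC = 27, Q = 46.4, VT = 87.6)
  expect_identical(individual_params(th, rep(0, 4)), th)
  expect_equal(individual_params(c(CL = 38.5), c(CL = log(2)))[["CL"]], 77.0)
  # strictly positive for extreme eta
  expect_true(all(individual_params(th, rep(-40, 4)) > 0))
  # median of P_i converges to theta under eta ~ N(0, omega2)
  set.seed(5)
  p <- 38.5 * exp(rnorm(1e5, 0, sqrt(0.4)))
  expect_equal(median(p), 38.5, tolerance = 0.02)
})

test_that("proportional residual variance scales with the square of the prediction", {
  expect_equal(residual_variance(0, 0.0576), 0)
  # sigma = 0.24 at 1 ng/mL gives SD 0.24 ng/mL
  expect_equal(sqrt(residual_variance(1, 0.24^2)), 0.24)
  pred <- c(0.3, 1.7, 4)
  v <- residual_variance(pred, 0.05)
  expect_equal(v / v[1], (pred / pred[1])^2)
  expect_equal(residual_variance(pred, 0.3, "additive"), rep(0.3, 3))
  expect_error(residual_variance(-1, 0.05), "non-negative")
})

test_that("CV conversions are mutually inverse and use the declared conventions", {
  for (cv in c(24, 63.2, 89, 124)) {
    expect_equal(omega2_to_cv(cv_to_omega2(cv)), cv, tolerance = 1e-12)
    expect_equal(omega2_to_cv(cv_to_omega2(cv, "sqrt"), "sqrt"), cv, tolerance = 1e-12)
    expect_equal(sigma2_to_cv(cv_to_sigma2(cv)), cv, tolerance = 1e-12)
  }
  expect_equal(omega2_to_cv(0.3361), 100 * sqrt(exp(0.3361) - 1), tolerance = 1e-12)
  expect_gt(omega2_to_cv(0.5), omega2_to_cv(0.5, "sqrt"))  # exact lognormal CV is larger
})

test_that("model constructor enforces its invariants", {
  expect_error(poppk_model(theta = c(CL = -1, VC = 30, Q = 40, VT = 90)), "positive")
  expect_error(poppk_model(theta = c(CL = 39, VC = 30)), "name all of")
  expect_error(poppk_model(sigma2 = 0), "sigma2")
  expect_error(poppk_model(omega2 = c(CL = -0.1)), "non-negative")
  dup <- list(covariate_term("CL", "WT", "power", ref = 75),
              covariate_term("CL", "WT", "linear", ref = 75))
  expect_error(poppk_model(covariates = dup), "at most one covariate term")
  expect_error(covariate_term("CL", "WT", "power", ref = NULL), "reference")
  expect_error(covariate_term("CL", "WT", "power", ref = -5), "positive reference")
  m1 <- poppk_model(theta = c(CL = 39, VC = 30), ncomp = 1)
  expect_identical(names(m1$theta), c("CL", "VC"))
})

test_that("covariate forms scale typical values as specified", {
  m <- table2_model()
  cov_df <- data.frame(WT = c(45, 75, 100), SEX = c(1, 0, 1))
  # power weight on CL with beta 0.75 spans (45/75)^0.75 .. (100/75)^0.75
  mp <- apply_covariate(m, covariate_term("CL", "WT", "power", 0.75, ref = 75))
  th <- dexpoppk:::typical_value_matrix(mp, cov_df)
  expect_equal(th[, "CL"] / 38.5, (cov_df$WT / 75)^0.75, tolerance = 1e-12)
  expect_equal(unname(th[2, "CL"]), 38.5)   # x = ref leaves theta unchanged
  # linear and indicator forms
  ml <- apply_covariate(m, covariate_term("VC", "WT", "linear", 0.01, ref = 75))
  thl <- dexpoppk:::typical_value_matrix(ml, cov_df)
  expect_equal(thl[, "VC"], 27 * (1 + 0.01 * (cov_df$WT - 75)), tolerance = 1e-12)
  mi <- apply_covariate(m, covariate_term("Q", "SEX", "indicator", -0.2))
  thi <- dexpoppk:::typical_value_matrix(mi, cov_df)
  expect_equal(thi[, "Q"], 46.4 * (1 - 0.2 * cov_df$SEX), tolerance = 1e-12)
  # beta = 0 reproduces the base model exactly
  m0 <- apply_covariate(m, covariate_term("CL", "WT", "power", 0, ref = 75))
  expect_equal(dexpoppk:::typical_value_matrix(m0, cov_df),
               dexpoppk:::typical_value_matrix(m, cov_df))
  # non-positive multipliers invalidate the candidate
  mneg <- apply_covariate(m, covariate_term("CL", "WT", "linear", -0.1, ref = 75))
  expect_null(dexpoppk:::typical_value_matrix(mneg, cov_df))
})
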