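# stepwise covariate search: screening gate, forward/backward mechanics

fake_fit_with_shrinkage <- function(shr) {
  # minimal object honouring the screen_parameters contract
  n <- 50
  eta <- sapply(names(shr), function(k) {
    if (is.na(shr[[k]])) rep(0, n) else rnorm(n, 0, 0.5 * (1 - shr[[k]] / 100))
  })
  fit <- structure(list(model = poppk_model(omega2 = setNames(rep(0.25, 4),
                                                              c("CL", "VC", "Q", "VT"))),
                        eta = eta, shrinkage = shr), class = "poppk")
  fit
}

test_that("the shrinkage gate is a strict 25% threshold", {
  shr <- c(CL = 0.0, VC = 17.6, Q = 10.6, VT = 23.6)
  fit <- fake_fit_with_shrinkage(shr)
  expect_setequal(screen_parameters(fit), c("CL", "VC", "Q", "VT"))
  shr2 <- c(CL = 25.0, VC = 24.99, Q = 60, VT = NA)
  fit2 <- fake_fit_with_shrinkage(shr2)
  expect_warning(out <- screen_parameters(fit2), "excluded")
  expect_identical(out, "VC")   # 25.0 exactly is excluded; NA excluded with warning
})

test_that("forward selection with no candidates returns the base fit unchanged", {
  tab <- one_comp_cohort(n = 12, seed = 1)
  fit <- poppk(tab, model = one_comp_init(), control = fast_control())
  out <- forward_selection(fit, list())
  expect_equal(nrow(out$trace), 0)
  expect_identical(out$fit$ofv, fit$ofv)
  out2 <- backward_elimination(fit)
  expect_equal(nrow(out2$trace), 0)
  expect_length(out2$fit$model$covariates, 0)
})

test_that("a strong weight effect on clearance is found and survives elimination", {
  # moderate unexplained IIV so the weight effect carries a clear signal
  sel_first <- 0
  reps <- 4
  for (r in seq_len(reps)) {
    tab <- one_comp_cohort(n = 50, beta_wt = 0.75, seed = 100 + r,
                           omega2 = c(0.05, 0.2))
    fit <- poppk(tab, model = one_comp_init(), control = fast_control())
    cs <- covariate_search(fit, covariates = "WT", forms = "power")
    sel <- cs$selected
    if (length(sel) >= 1 &&
        any(vapply(sel, function(s) s$parameter == "CL" && s$covariate == "WT", TRUE)))
      sel_first <- sel_first + 1
  }
  expect_gte(sel_first, reps - 1)
})

test_that("a weak term is eliminated backward but a strong one is retained", {
  tab <- one_comp_cohort(n = 50, beta_wt = 0.75, seed = 302,
                         omega2 = c(0.05, 0.2))
  base <- poppk(tab, model = one_comp_init(), control = fast_control())
  ref <- median(as.data.frame(tab)$WT)
  # strong true effect: removal costs well over the threshold
  strong <- poppk(tab, model = apply_covariate(base$model,
                                               covariate_term("CL", "WT", "power", 0.75, ref = ref)),
                  control = fast_control())
  out <- backward_elimination(strong)
  expect_length(out$fit$model$covariates, 1)
  expect_gt(out$trace$delta_ofv[out$trace$decision == "tested"][1],
            selection_thresholds()[["backward"]])
  # spurious term on a null dataset: removal is cheap, term dropped
  tab0 <- one_comp_cohort(n = 20, beta_wt = 0, seed = 302)
  base0 <- poppk(tab0, model = one_comp_init(), control = fast_control())
  spur <- poppk(tab0, model = apply_covariate(base0$model,
                                              covariate_term("VC", "WT", "linear", 0, ref = ref)),
                control = fast_control())
  out0 <- backward_elimination(spur)
  expect_length(out0$fit$model$covariates, 0)
})

test_that("the forward trace decreases in OFV and logs every candidate fit", {
  tab <- one_comp_cohort(n = 30, beta_wt = 0.9, seed = 41,
                         omega2 = c(0.05, 0.2))
  fit <- poppk(tab, model = one_comp_init(), control = fast_control())
  cs <- covariate_search(fit, covariates = "WT")
  incl <- cs$trace[cs$trace$decision == "included", ]
  if (nrow(incl) > 1) expect_true(all(diff(incl$ofv) < 0))
  expect_true(all(cs$trace$decision %in%
                  c("tested", "included", "removed", "skipped (non-convergence)")))
  f <- tempfile(fileext = ".csv")
  write_search_trace(cs, f)
  expect_true(file.exists(f))
  expect_identical(names(read.csv(f))[1:3], c("step", "phase", "parameter"))
})
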