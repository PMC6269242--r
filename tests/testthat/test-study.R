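small_cfg <- function(..., reps = 10) {
  study_config(n = 600, reps = reps, seed = 5, truth_n = 3e4,
               mice_m = 3, mice_maxit = 2, ...)
}

test_that("identical config and seed reproduce the study result exactly", {
  cfg <- small_cfg(mdags = c("A", "D"), methods = c("available_case", "complete_case"))
  r1 <- run_study(cfg)
  r2 <- run_study(cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_setequal(r1$mdag, c("A", "D"))
  expect_true(all(r1$coverage >= 0 & r1$coverage <= 1))
  expect_equal(r1$bias_mcse, r1$empirical_se / sqrt(r1$reps))
})

test_that("near-zero missingness control shows no detectable bias anywhere", {
  cfg <- small_cfg(mdags = "J", reps = 20,
                   methods = c("available_case", "complete_case", "mice"),
                   targets = c(M_Z2 = 1e-4, M_X = 1e-4, M_Y = 1e-4))
  res <- run_study(cfg)
  ## the reference truth is itself a finite-sample quantity: allow for its
  ## Monte Carlo error alongside the replicate-mean error
  truth_se <- res$empirical_se * sqrt(cfg$n / cfg$truth_n)
  expect_true(all(abs(res$bias) < 3 * (res$bias_mcse + truth_se)))
  ## with essentially no missingness, all methods coincide with the
  ## full-data estimator
  for (p in unique(res$parameter)) {
    ests <- res$mean_estimate[res$parameter == p]
    expect_lt(diff(range(ests)), 0.02 * max(1, abs(res$truth[res$parameter == p][1])))
  }
  checks <- qualitative_checks(res)
  expect_equal(checks$status[checks$finding == "mean_bias_exceeds_association_bias"],
               "not_evaluable")
})

test_that("qualitative checks classify constructed results correctly", {
  row <- function(mdag, parameter, method, bias, truth = 1, mcse = 0.001) {
    data.frame(mdag = mdag, parameter = parameter, method = method, truth = truth,
               mean_estimate = truth + bias, bias = bias, empirical_se = mcse * 10,
               mean_model_se = mcse * 10, coverage = 0.95, reps = 100,
               bias_mcse = mcse, failed = FALSE, stringsAsFactors = FALSE)
  }
  res <- rbind(
    row("D", "expectation_X", "available_case", bias = 0.05, truth = 0.2),
    row("D", "regression_coefficient", "complete_case", bias = 0.002),
    row("A", "expectation_X", "mice", bias = 0.0005, truth = 0.2),
    row("A", "regression_coefficient", "mice", bias = 0.0008))
  strong <- row("H", "regression_coefficient", "complete_case", bias = 0.08)
  default <- rbind(res, row("H", "regression_coefficient", "complete_case", bias = 0.01))
  ch <- qualitative_checks(default, strong_result = strong)
  expect_equal(ch$status[ch$finding == "mean_bias_exceeds_association_bias"], "pass")
  expect_equal(ch$status[ch$finding == "mice_unbiased_recoverable"], "pass")
  expect_equal(ch$status[ch$finding == "mdagH_association_bias_grows_when_strong"], "pass")

  ## a biased recoverable MICE cell flips finding (ii)
  bad <- rbind(res[1:3, ], row("A", "regression_coefficient", "mice", bias = 0.05))
  ch2 <- qualitative_checks(bad)
  expect_equal(ch2$status[ch2$finding == "mice_unbiased_recoverable"], "fail")
  expect_equal(ch2$status[ch2$finding == "mdagH_association_bias_grows_when_strong"],
               "not_evaluable")
})

test_that("config validation catches unusable settings", {
  expect_error(study_config(reps = 1), "reps")
  expect_error(study_config(methods = "bootstrap"), "unknown method")
})
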