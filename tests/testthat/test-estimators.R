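# hand-buildable incomplete dataset: binary Z1, Z2, X and Y with explicit
# masks; indicators are set from the masks and values blanked accordingly
toy_data <- function(z1, z2, x, y, m_z2 = 0, m_x = 0, m_y = 0) {
  n <- length(z1)
  d <- data.frame(Z1 = z1, Z2 = z2, X = x, Y = y,
                  M_Z2 = rep_len(m_z2, n), M_X = rep_len(m_x, n), M_Y = rep_len(m_y, n))
  d$Z2[d$M_Z2 == 1] <- NA; d$X[d$M_X == 1] <- NA; d$Y[d$M_Y == 1] <- NA
  structure(d, class = c("incomplete_data", "data.frame"),
            schema = list(z1 = "Z1", z2 = "Z2", x = "X", y = "Y", y_type = "binary"))
}

test_that("available-case mean: exactness without missingness, hand oracle with", {
  d <- toy_data(z1 = rep(0:1, 5), z2 = rep(0, 10), x = c(1, 0, 1, 1, 0, 1, 0, 0, 1, 1),
                y = rep(0, 10))
  e <- available_case_mean(d, "X")
  expect_identical(e$estimate, mean(c(1, 0, 1, 1, 0, 1, 0, 0, 1, 1)))

  d2 <- toy_data(z1 = rep(0:1, 5), z2 = rep(0, 10), x = c(1, 0, 1, 1, 0, 1, 0, 0, 1, 1),
                 y = rep(0, 10), m_x = c(1, 0, 0, 1, 0, 0, 0, 1, 0, 0))
  e2 <- available_case_mean(d2, "X")
  expect_equal(e2$estimate, mean(c(0, 1, 0, 1, 0, 1, 1)))   # the 7 observed values
  expect_equal(e2$se, stats::sd(c(0, 1, 0, 1, 0, 1, 1)) / sqrt(7))

  d3 <- toy_data(1, 1, 1, 1, m_x = 1)
  expect_error(available_case_mean(d3, "X"), "estimation error")
})

test_that("complete-case regression equals the full-data fit when nothing is missing", {
  d <- simulate_mdag("A", 800, seed = 40)
  full <- attr(d, "complete")
  sch <- attr(d, "schema")
  nomiss <- full
  nomiss$M_Z2 <- 0; nomiss$M_X <- 0; nomiss$M_Y <- 0
  nomiss <- structure(nomiss, class = c("incomplete_data", "data.frame"), schema = sch)
  got <- complete_case_regression(nomiss)
  want <- stats::lm(Y ~ X + Z1a + Z1b + Z2a + Z2b, data = full)
  expect_equal(got$estimate, unname(stats::coef(want)["X"]))
  expect_equal(got$se, unname(sqrt(diag(stats::vcov(want))["X"])))
})

test_that("standardization over Z1 matches the hand-computed 2x2x2 table", {
  ## counts by (Z1, X): Z1=0: X observed {1,1,0,0,0} and 3 masked;
  ##                    Z1=1: X observed {1,0} and 1 masked
  d <- toy_data(z1 = c(rep(0, 8), rep(1, 3)),
                z2 = 0,
                x = c(1, 1, 0, 0, 0, 9, 9, 9, 1, 0, 9),
                y = 0,
                m_x = c(0, 0, 0, 0, 0, 1, 1, 1, 0, 0, 1))
  out <- standardized_marginal(d, "X")
  want <- (8 / 11) * (2 / 5) + (3 / 11) * (1 / 2)   # sum_z P(X=1|z, obs) P(z)
  expect_equal(out$estimate$estimate, want)
  expect_equal(out$distribution$p[out$distribution$value == 1], want)
  ## closed-form stratified SE
  want_se <- sqrt((8 / 11)^2 * stats::var(c(1, 1, 0, 0, 0)) / 5 +
                  (3 / 11)^2 * stats::var(c(1, 0)) / 2)
  expect_equal(out$estimate$se, want_se)
})

test_that("empty strata are reported by name", {
  d <- toy_data(z1 = c(0, 0, 1, 1), z2 = 0, x = c(1, 0, 9, 9), y = 0,
                m_x = c(0, 0, 1, 1))
  expect_error(standardized_marginal(d, "X"), "empty stratum.*1")
})

test_that("standardization agrees with the available-case mean under MCAR", {
  m <- binary_model()
  mech <- missingness_mechanism("A", m)
  for (mi in names(mech$coefs)) mech$coefs[[mi]][] <- 0
  mech <- calibrate_intercepts(mech, m, seed = 50)
  d <- apply_missingness(gen_complete(m, 4e4, seed = 51), mech, seed = 52)
  expect_lt(abs(standardized_marginal(d, "Y")$estimate$estimate -
                  available_case_mean(d, "Y")$estimate), 0.01)
})

test_that("plug-in joint without missingness is the empirical joint", {
  m <- binary_model()
  cmp <- gen_complete(m, 3000, seed = 60)
  mech <- missingness_mechanism("A", m)
  mech$intercepts[] <- -50
  d <- apply_missingness(cmp, mech, seed = 61)
  j <- plugin_joint_A(d)
  emp <- stats::aggregate(rep(1 / nrow(d), nrow(d)),
                          as.data.frame(d)[c("Z1", "Z2", "X", "Y")], sum)
  names(emp)[5] <- "p"
  mrg <- merge(as.data.frame(j), emp, by = c("Z1", "Z2", "X", "Y"))
  expect_equal(mrg$p.x, mrg$p.y, tolerance = 1e-12)
})

test_that("marginalizing the plug-in joint reproduces the standardized marginal", {
  ## with missingness confined to X, the complete cases coincide with the
  ## X-observed records and the two estimators are algebraically identical
  m <- binary_model()
  mech <- calibrate_intercepts(missingness_mechanism("A", m), m, seed = 70, n = 5e4)
  mech$intercepts[c("M_Z2", "M_Y")] <- -50
  d <- apply_missingness(gen_complete(m, 2e4, seed = 71), mech, seed = 72)
  j <- plugin_joint_A(d)
  mx <- dj_margin(j, "X")
  std <- standardized_marginal(d, "X")
  expect_equal(mx$p[mx$X == 1],
               std$distribution$p[std$distribution$value == 1], tolerance = 1e-12)
})

new_dj_from <- function(df) {
  structure(df, class = c("discrete_joint", "data.frame"))
}

test_that("constant observation probabilities make IPW collapse to the complete-case joint", {
  m <- binary_model()
  mech <- missingness_mechanism("B", m)
  for (mi in names(mech$coefs)) mech$coefs[[mi]][] <- 0
  mech$intercepts[] <- stats::qlogis(0.2)
  d <- apply_missingness(gen_complete(m, 2e4, seed = 80), mech, seed = 81)
  ## exact identity when the estimated factor is a single constant: condition
  ## on a degenerate column so the fitted observation probability is flat
  d$ones <- 1
  f <- estimand_formula("sequential_ipw", target_vars = c("Z1", "Z2", "X", "Y"),
                        factors = list(
                          list(indicator = "M_Y", cond = "ones", restrict = c("M_Z2", "M_X")),
                          list(indicator = "M_Z2", cond = "ones", restrict = "M_X"),
                          list(indicator = "M_X", cond = "ones", restrict = "M_Z2")))
  j0 <- sequential_ipw_joint(d, f)
  cc <- d[d$M_Z2 == 0 & d$M_X == 0 & d$M_Y == 0, ]
  emp <- stats::aggregate(rep(1 / nrow(cc), nrow(cc)),
                          as.data.frame(cc)[c("Z1", "Z2", "X", "Y")], sum)
  names(emp)[5] <- "p"
  mrg <- merge(as.data.frame(j0), emp, by = c("Z1", "Z2", "X", "Y"))
  expect_equal(mrg$p.x, mrg$p.y, tolerance = 1e-12)
  ## the full row-B factorization agrees up to sampling noise in the factors
  j <- sequential_ipw_joint(d, verdict("B", "joint")$formula)
  expect_lt(tv_distance(j, new_dj_from(emp)), 0.01)
})

test_that("IPW weights on a worked fixture match hand arithmetic", {
  ## single factor P(M_X = 0 | Z1): 3/4 observed when Z1 = 0, 1/2 when Z1 = 1
  d <- toy_data(z1 = c(0, 0, 0, 0, 1, 1, 1, 1), z2 = 0,
                x = c(1, 1, 0, 9, 1, 0, 9, 9), y = 0,
                m_x = c(0, 0, 0, 1, 0, 0, 1, 1))
  f <- estimand_formula("sequential_ipw", target_vars = c("Z1", "X"),
                        factors = list(list(indicator = "M_X", cond = "Z1",
                                            restrict = character(0))))
  j <- sequential_ipw_joint(d, f)
  ## unnormalized cells: (z1=0,x=1): 2/8 / (3/4); (0,0): 1/8 / (3/4);
  ## (1,1): 1/8 / (1/2); (1,0): 1/8 / (1/2); total = 1
  expect_equal(j$p[j$Z1 == 0 & j$X == 1], (2 / 8) / (3 / 4))
  expect_equal(j$p[j$Z1 == 1 & j$X == 0], (1 / 8) / (1 / 2))
})

test_that("the positivity floor truncates and warns", {
  set.seed(90)
  n <- 4000
  z1 <- rbinom(n, 1, 0.5)
  mx <- ifelse(z1 == 1, rbinom(n, 1, 0.999), rbinom(n, 1, 0.05))
  d <- toy_data(z1 = z1, z2 = 0, x = rbinom(n, 1, 0.4), y = 0, m_x = mx)
  f <- estimand_formula("sequential_ipw", target_vars = c("Z1", "X"),
                        factors = list(list(indicator = "M_X", cond = "Z1",
                                            restrict = character(0))))
  expect_warning(j <- sequential_ipw_joint(d, f), "positivity")
  expect_gt(attr(j, "truncated"), 0)
})

test_that("estimate_target refuses nonrecoverable requests", {
  d <- simulate_mdag("D", 500, seed = 95, model = binary_model())
  expect_error(estimate_target(d, "D", "expectation_X"), "sensitivity analysis")
  expect_error(estimate_target(d, "J", "joint"), "nonrecoverable")
})
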