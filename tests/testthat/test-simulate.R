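# numeric-integration oracle for the exposure prevalence implied by the
# default model: integrate the logistic structural equation over the latent
# sources (L, U) and the continuous confounder's idiosyncratic noise, and
# sum over the binary confounder patterns
oracle_prevalence <- function(model, k = 61) {
  gr <- seq(-6, 6, length.out = k)
  w <- stats::dnorm(gr); w <- w / sum(w)
  zb <- expand.grid(Z1a = 0:1, Z2a = 0:1, Z2b = 0:1)
  total <- 0
  for (iL in seq_len(k)) {
    L <- gr[iL]
    p1 <- stats::plogis(model$z1$Z1a$intercept + model$z1$Z1a$l * L)
    p2 <- stats::plogis(model$z2$Z2a$intercept + model$z2$Z2a$l * L)
    p3 <- stats::plogis(model$z2$Z2b$intercept + model$z2$Z2b$l * L)
    for (ib in seq_len(nrow(zb))) {
      r <- zb[ib, ]
      wz <- (if (r$Z1a == 1) p1 else 1 - p1) * (if (r$Z2a == 1) p2 else 1 - p2) *
        (if (r$Z2b == 1) p3 else 1 - p3)
      base <- model$x$intercept + model$x$coef[["Z1a"]] * r$Z1a +
        model$x$coef[["Z2a"]] * r$Z2a + model$x$coef[["Z2b"]] * r$Z2b
      ## Z1b = l*L + sd*eps and U are one more 2-d integral
      z1b <- model$z1$Z1b$l * L + model$z1$Z1b$sd * gr
      lp <- outer(base + model$x$coef[["Z1b"]] * z1b, model$x$coef[["U"]] * gr, `+`)
      total <- total + w[iL] * wz * sum(stats::plogis(lp) * outer(w, w))
    }
  }
  total
}

test_that("generation is reproducible and seed-sensitive", {
  m <- cohort_model()
  d1 <- gen_complete(m, 200, seed = 9)
  d2 <- gen_complete(m, 200, seed = 9)
  expect_identical(d1, d2)
  expect_false(identical(gen_complete(m, 200, seed = 10), d1))
  i1 <- simulate_mdag("B", 300, seed = 4)
  i2 <- simulate_mdag("B", 300, seed = 4)
  expect_identical(as.data.frame(i1), as.data.frame(i2))
})

test_that("null-effects exposure model reduces to its intercept", {
  m <- cohort_model()
  m$x$coef[] <- 0
  m$x$intercept <- stats::qlogis(0.3)
  d <- gen_complete(m, 2e4, seed = 3)
  expect_lt(abs(mean(d$X) - 0.3), 0.012)
  ## and independence of the confounders within MC error
  expect_lt(abs(mean(d$X[d$Z1a == 1]) - mean(d$X[d$Z1a == 0])), 0.02)
})

test_that("default model hits the targeted exposure prevalence", {
  m <- cohort_model()
  truth <- oracle_prevalence(m)
  expect_lt(abs(truth - 0.21), 0.005)          # the preset targets 21%
  d <- gen_complete(m, 4e5, seed = 1)
  expect_lt(abs(mean(d$X) - truth), 0.005)     # generator agrees with quadrature
  expect_lt(abs(mean(d$Y) - 7.5), 0.05)
  expect_lt(abs(stats::sd(d$Y) - 3), 0.05)
})

test_that("intercept calibration: closed form under null slopes, targets otherwise", {
  m <- cohort_model()
  mech <- missingness_mechanism("A", m)
  for (mi in names(mech$coefs)) mech$coefs[[mi]][] <- 0
  mech <- calibrate_intercepts(mech, m, targets = c(M_X = 0.15), seed = 2)
  expect_equal(mech$intercepts[["M_X"]], stats::qlogis(0.15), tolerance = 1e-6)

  mech2 <- calibrate_intercepts(missingness_mechanism("A", m), m, seed = 2)
  d <- apply_missingness(gen_complete(m, 2e5, seed = 21), mech2, seed = 22)
  props <- attr(d, "miss_props")
  expect_lt(abs(props[["M_Z2"]] - 0.19), 0.01)
  expect_lt(abs(props[["M_X"]] - 0.15), 0.01)
  expect_lt(abs(props[["M_Y"]] - 0.23), 0.01)
  ## out-of-sample: a fresh seed reproduces the targets
  d2 <- apply_missingness(gen_complete(m, 2e5, seed = 31), mech2, seed = 32)
  expect_true(all(abs(attr(d2, "miss_props") - c(0.19, 0.15, 0.23)) < 0.01))
})

test_that("calibration holds across all ten canonical presets", {
  m <- cohort_model()
  for (id in canonical_ids()) {
    mech <- calibrate_intercepts(missingness_mechanism(id, m), m, seed = 5, n = 5e4)
    d <- apply_missingness(gen_complete(m, 5e4, seed = 6), mech, seed = 7)
    expect_true(all(abs(attr(d, "miss_props") - c(0.19, 0.15, 0.23)) < 0.015),
                label = paste("calibration for m-DAG", id))
  }
})

test_that("degenerate missingness leaves the data untouched", {
  m <- cohort_model()
  mech <- missingness_mechanism("A", m)
  mech$intercepts[] <- -50
  cmp <- gen_complete(m, 500, seed = 8)
  d <- apply_missingness(cmp, mech, seed = 9)
  expect_equal(sum(d$M_Z2 + d$M_X + d$M_Y), 0)
  expect_identical(d$Y, cmp$Y)
  expect_false(anyNA(d))
})

test_that("mechanism support is checked against the graph", {
  m <- cohort_model()
  expect_error(missingness_mechanism("A", m, slopes = list(M_X = c(Y = 0.5))),
               "non-parent")
  ## under m-DAG A no substantive variable beyond Z1 enters any indicator
  mech <- missingness_mechanism("A", m)
  expect_setequal(names(mech$coefs$M_Y), c("Z1a", "Z1b", "W"))
  ## under m-DAG J everything does
  mechJ <- missingness_mechanism("J", m)
  expect_setequal(names(mechJ$coefs$M_Y), c("Z1a", "Z1b", "Z2a", "Z2b", "X", "Y", "W"))
})

test_that("the Z2 block is masked jointly", {
  d <- simulate_mdag("A", 2000, seed = 13)
  gone <- d$M_Z2 == 1
  expect_true(all(is.na(d$Z2a[gone])) && all(is.na(d$Z2b[gone])))
  expect_false(anyNA(d$Z2a[!gone]) || anyNA(d$Z2b[!gone]))
  expect_false(any(c("L", "U", "W") %in% names(d)))
})

test_that("refitting the missingness model recovers the planted mechanism", {
  ## refit oracle on generated data: regress each indicator on the full
  ## structural parent candidates (including the latent W, available from
  ## the pre-masking complete data) and compare with the planted slopes
  m <- cohort_model()
  refit_MY <- function(id, seed) {
    mech <- calibrate_intercepts(missingness_mechanism(id, m), m, seed = seed)
    cmp <- gen_complete(m, 2e5, seed + 1)
    d <- apply_missingness(cmp, mech, seed + 2)
    fit <- stats::glm(d$M_Y ~ Z1a + Z1b + Z2a + Z2b + X + Y + W, data = cmp,
                      family = stats::binomial())
    list(cf = summary(fit)$coefficients, mech = mech)
  }
  rA <- refit_MY("A", 170)
  ## planted: X, Z2, Y slopes are zero under m-DAG A
  for (v in c("X", "Z2a", "Z2b", "Y")) expect_lt(abs(rA$cf[v, "z value"]), 3.5)

  rJ <- refit_MY("J", 180)
  ## planted per-SD log-odds on Y (outcome SD about 3), recovered within 2 SE
  expect_lt(abs(rJ$cf["Y", "Estimate"] - rJ$mech$coefs$M_Y[["Y"]]),
            2 * rJ$cf["Y", "Std. Error"])
  expect_lt(abs(rJ$cf["X", "Estimate"] - rJ$mech$coefs$M_Y[["X"]]),
            2 * rJ$cf["X", "Std. Error"])
})
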