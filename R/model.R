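#' Complete-data generative model for a point-exposure study
#'
#' Describes the structural equations of the canonical complete-data DAG:
#' latent standard-normal sources `L` (shared dependence between the
#' confounder blocks), `U` (unmeasured exposure-outcome confounder) and `W`
#' (unmeasured common cause of missingness, drawn here but used only by the
#' missingness mechanism); complete confounders `Z1` and incomplete
#' confounders `Z2`; a binary exposure `X` with a logistic main-effects
#' model in the confounders and `U`; and an outcome `Y`, either continuous
#' (linear main effects plus normal noise) or binary (logistic).
#'
#' @param z1,z2 named lists of component specifications. Binary components:
#'   `list(type = "binary", intercept =, l =)` where `l` is the loading on
#'   the shared latent `L`. Normal components: `list(type = "normal", l =,
#'   sd =)` (marginal variance `l^2 + sd^2`).
#' @param x `list(intercept =, coef =)` with `coef` a named vector over
#'   `Z1`/`Z2` component names and `"U"`.
#' @param y `list(type = "continuous"|"binary", intercept =, coef =, sd =)`
#'   with `coef` named over `"X"`, confounder components and `"U"`; `sd` is
#'   the residual standard deviation in continuous mode.
#' @return an object of class `complete_data_model`.
#' @seealso [cohort_model()], [binary_model()], [gen_complete()]
#' @export
complete_data_model <- function(z1, z2, x, y) {
  zvars <- c(names(z1), names(z2))
  assert_that(!anyDuplicated(zvars), "duplicate confounder component names")
  check_spec <- function(s, nm) {
    assert_that(s$type %in% c("binary", "normal"), paste("bad type for", nm))
    if (s$type == "normal") assert_that(s$sd > 0, paste("sd must be > 0 for", nm))
  }
  for (nm in names(z1)) check_spec(z1[[nm]], nm)
  for (nm in names(z2)) check_spec(z2[[nm]], nm)
  assert_that(all(names(x$coef) %in% c(zvars, "U")),
              "exposure model uses a parent absent from the c-DAG")
  assert_that(all(names(y$coef) %in% c("X", zvars, "U")),
              "outcome model uses a parent absent from the c-DAG")
  assert_that(all(is.finite(c(x$intercept, x$coef, y$intercept, y$coef))),
              "model coefficients must be finite")
  y$type <- y$type %||% "continuous"
  if (y$type == "continuous") assert_that(is.numeric(y$sd) && y$sd > 0, "outcome noise SD must be > 0")
  structure(list(z1 = z1, z2 = z2, x = x, y = y), class = "complete_data_model")
}

#' @export
print.complete_data_model <- function(x, ...) {
  cat("complete-data model: Z1 = (", paste(names(x$z1), collapse = ", "),
      "), Z2 = (", paste(names(x$z2), collapse = ", "), "), binary X, ",
      x$y$type, " Y\n", sep = "")
  invisible(x)
}

model_schema <- function(model) {
  list(z1 = names(model$z1), z2 = names(model$z2), x = "X", y = "Y",
       y_type = model$y$type)
}

## approximate marginal SD of each analysis column, used to put missingness
## log-odds on a per-SD scale for continuous parents; binary columns get 1
## (odds ratio per unit). Covariances between parents are ignored: this is a
## scale, not a moment calculation.
model_column_sd <- function(model) {
  zs <- c(model$z1, model$z2)
  zsd <- vapply(names(zs), function(nm) {
    s <- zs[[nm]]
    if (s$type == "normal") sqrt(s$l^2 + s$sd^2) else 1
  }, 1)
  zvar <- vapply(names(zs), function(nm) {
    s <- zs[[nm]]
    if (s$type == "normal") s$l^2 + s$sd^2 else 0.25
  }, 1)
  ysd <- if (model$y$type == "continuous") {
    pvar <- c(X = 0.25, zvar, U = 1)
    sqrt(model$y$sd^2 + sum(model$y$coef^2 * pvar[names(model$y$coef)]))
  } else 1
  c(zsd, X = 1, Y = unname(ysd), W = 1)
}

#' Default study-like generative model
#'
#' A mixed complete-data model emulating a birth-cohort point-exposure
#' analysis: two complete confounders (one binary, one standard-normal
#' continuous), two binary incomplete confounders (prevalence about 0.2),
#' a binary exposure calibrated to about 21\% prevalence, and a continuous
#' outcome scaled to mean about 7.5 and standard deviation about 3 (a
#' behavioural-difficulties score). The exposure-outcome effect of 0.6 on
#' the outcome scale plus confounding through `Z1`, `Z2` and `U` yields a
#' complete-data regression-adjusted association of about 1.1.
#'
#' @return a [complete_data_model()].
#' @export
cohort_model <- function() {
  complete_data_model(
    z1 = list(Z1a = list(type = "binary", intercept = 0, l = 0.8),
              Z1b = list(type = "normal", l = 0.6, sd = 0.8)),
    z2 = list(Z2a = list(type = "binary", intercept = -1.4, l = 0.8),
              Z2b = list(type = "binary", intercept = -1.4, l = 0.8)),
    x = list(intercept = -2.2681,
             coef = c(Z1a = log(2), Z1b = log(1.5), Z2a = log(2), Z2b = log(2),
                      U = log(2))),
    y = list(type = "continuous", intercept = 6.6132,
             coef = c(X = 0.6, Z1a = 0.8, Z1b = 0.8, Z2a = 0.8, Z2b = 0.8, U = 0.8),
             sd = 2.5708))
}

#' All-binary generative model
#'
#' A fully discrete complete-data model (binary `Z1`, `Z2`, `X`, `Y`) for
#' which every joint and marginal distribution has finite support, so that
#' the plug-in and sequential-IPW identification formulas can be evaluated
#' as frequency tables and compared with the exact model-implied joint
#' ([true_joint()]).
#'
#' @return a [complete_data_model()].
#' @export
binary_model <- function() {
  complete_data_model(
    z1 = list(Z1 = list(type = "binary", intercept = 0, l = 0.8)),
    z2 = list(Z2 = list(type = "binary", intercept = -0.5, l = 0.8)),
    x = list(intercept = -1.8, coef = c(Z1 = 0.7, Z2 = 0.7, U = 0.7)),
    y = list(type = "binary", intercept = -1.2,
             coef = c(X = 0.6, Z1 = 0.7, Z2 = 0.7, U = 0.7)))
}

#' Generate complete data under a complete-data model
#'
#' @param model a [complete_data_model()].
#' @param n number of records.
#' @param seed integer seed; generation is reproducible and leaves the
#'   caller's RNG state untouched.
#' @return a data.frame with the latent columns `L`, `U`, `W`, the
#'   confounder components, `X` and `Y`; the schema is attached as an
#'   attribute. The latent columns never enter the visible data produced by
#'   [apply_missingness()].
#' @export
gen_complete <- function(model, n, seed) {
  assert_that(inherits(model, "complete_data_model"), "model must be a complete_data_model")
  assert_that(n >= 1, "n must be at least 1")
  with_seed(seed, {
    L <- stats::rnorm(n); U <- stats::rnorm(n); W <- stats::rnorm(n)
    dat <- data.frame(L = L, U = U, W = W)
    for (nm in names(model$z1)) dat[[nm]] <- draw_z(model$z1[[nm]], L, n)
    for (nm in names(model$z2)) dat[[nm]] <- draw_z(model$z2[[nm]], L, n)
    lpx <- model$x$intercept + linpred(dat, model$x$coef)
    dat$X <- stats::rbinom(n, 1, stats::plogis(lpx))
    lpy <- model$y$intercept + linpred(dat, model$y$coef)
    if (model$y$type == "continuous") {
      dat$Y <- lpy + stats::rnorm(n, sd = model$y$sd)
    } else {
      dat$Y <- stats::rbinom(n, 1, stats::plogis(lpy))
    }
    attr(dat, "schema") <- model_schema(model)
    dat
  })
}

draw_z <- function(spec, L, n) {
  if (spec$type == "binary") {
    stats::rbinom(n, 1, stats::plogis(spec$intercept + spec$l * L))
  } else {
    spec$l * L + stats::rnorm(n, sd = spec$sd)
  }
}

linpred <- function(dat, coef) {
  lp <- rep(0, nrow(dat))
  for (nm in names(coef)) lp <- lp + coef[[nm]] * dat[[nm]]
  lp
}

#' Exact joint distribution implied by an all-binary model
#'
#' Computes the model-implied joint probability of every cell of
#' `(Z1, Z2, X, Y)` for a fully binary [complete_data_model()], integrating
#' the logistic structural equations over the standard-normal latents `L`
#' and `U` on a fine grid. Used as the simulation truth in the formula
#' consistency checks.
#'
#' @param model an all-binary [complete_data_model()].
#' @param grid_points number of integration nodes per latent.
#' @return a `discrete_joint` table (see [plugin_joint_A()]).
#' @export
true_joint <- function(model, grid_points = 161) {
  sch <- model_schema(model)
  comps <- c(model$z1, model$z2)
  assert_that(all(vapply(comps, function(s) s$type, "") == "binary") &&
                model$y$type == "binary",
              "true_joint requires an all-binary model")
  zn <- c(sch$z1, sch$z2)
  cells <- expand.grid(stats::setNames(rep(list(0:1), length(zn) + 2), c(zn, "X", "Y")))
  gl <- .norm_grid(grid_points); gu <- .norm_grid(grid_points)
  ## P(cell) = E_L[ prod_z P(z|L) ] x E_U within: X,Y depend on U but not L
  ## given Z; integrate jointly over independent L and U.
  p <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    r <- cells[i, ]
    pz_l <- rep(1, length(gl$x))
    for (nm in zn) {
      s <- comps[[nm]]
      pr <- stats::plogis(s$intercept + s$l * gl$x)
      pz_l <- pz_l * if (r[[nm]] == 1) pr else 1 - pr
    }
    lpx <- model$x$intercept + sum(model$x$coef[zn][!is.na(model$x$coef[zn])] *
                                     unlist(r[names(model$x$coef[zn])[!is.na(model$x$coef[zn])]]))
    lpx_u <- lpx + (model$x$coef[["U"]] %||% 0) * gu$x
    px <- stats::plogis(lpx_u); px <- if (r$X == 1) px else 1 - px
    ynames <- intersect(names(model$y$coef), c("X", zn))
    lpy <- model$y$intercept + sum(model$y$coef[ynames] * unlist(r[ynames]))
    lpy_u <- lpy + (model$y$coef[["U"]] %||% 0) * gu$x
    py <- stats::plogis(lpy_u); py <- if (r$Y == 1) py else 1 - py
    p[i] <- sum(pz_l * gl$w) * sum(px * py * gu$w)
  }
  cells$p <- p / sum(p)
  structure(cells, class = c("discrete_joint", "data.frame"),
            provenance = "model-implied (numerical integration)")
}
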