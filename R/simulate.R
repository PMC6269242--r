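#' Missingness mechanism under a canonical m-DAG
#'
#' Builds main-effects logistic models for the three missingness indicators
#' `M_Z2`, `M_X`, `M_Y`, with coefficient support exactly equal to each
#' indicator's parent set in the chosen m-DAG. Graph-level parents map to
#' data columns: `Z1` and `Z2` to their components, `X`, `Y` to themselves
#' and `W` to the shared standard-normal latent. Default slopes are an odds
#' ratio of about 2 per unit for binary parents and per standard deviation
#' for continuous parents (the `"strong"` preset doubles the log odds, an
#' odds ratio of about 4); the `W` slope is fixed at `log(2)`.
#'
#' @param mdag_id canonical letter `"A"`-`"J"`, or an [mdag()].
#' @param model the [complete_data_model()] the mechanism will act on.
#' @param preset `"default"` or `"strong"` effect sizes for the arrows from
#'   substantive variables to indicators.
#' @param slopes optional named list overriding the coefficient vector of an
#'   indicator (named numeric vectors over that indicator's parent columns).
#' @param intercepts named numeric vector of logistic intercepts; usually
#'   left to [calibrate_intercepts()].
#' @param targets marginal missingness proportions for `M_Z2`, `M_X`, `M_Y`
#'   used by the calibration; defaults 0.19, 0.15 and 0.23.
#' @return an object of class `missingness_mechanism`.
#' @export
missingness_mechanism <- function(mdag_id, model, preset = c("default", "strong"),
                                  slopes = NULL, intercepts = NULL,
                                  targets = c(M_Z2 = 0.19, M_X = 0.15, M_Y = 0.23)) {
  preset <- match.arg(preset)
  g <- if (inherits(mdag_id, "mdag")) mdag_id else canonical(mdag_id)$mdag
  id <- if (inherits(mdag_id, "mdag")) NA_character_ else mdag_id
  sch <- model_schema(model)
  sds <- model_column_sd(model)
  scale <- if (preset == "strong") log(4) else log(2)
  col_map <- list(Z1 = sch$z1, Z2 = sch$z2, X = "X", Y = "Y", W = "W")
  coefs <- lapply(c(M_Z2 = "M_Z2", M_X = "M_X", M_Y = "M_Y"), function(m) {
    pa <- parents(g, m)
    cols <- unlist(col_map[intersect(names(col_map), pa)], use.names = FALSE)
    cf <- vapply(cols, function(cl) {
      if (cl == "W") log(2) else scale / sds[[cl]]
    }, 1)
    stats::setNames(cf, cols)
  })
  if (!is.null(slopes)) {
    for (m in names(slopes)) {
      extra <- setdiff(names(slopes[[m]]), names(coefs[[m]]))
      if (length(extra)) {
        stop("slope for non-parent column(s) of ", m, ": ", paste(extra, collapse = ", "),
             call. = FALSE)
      }
      coefs[[m]][names(slopes[[m]])] <- slopes[[m]]
    }
  }
  if (is.null(intercepts)) {
    intercepts <- stats::setNames(rep(NA_real_, 3), names(coefs))
  }
  structure(list(mdag_id = id, coefs = coefs, intercepts = intercepts,
                 targets = targets, preset = preset),
            class = "missingness_mechanism")
}

#' @export
print.missingness_mechanism <- function(x, ...) {
  cat("missingness mechanism (m-DAG ", x$mdag_id, ", preset ", x$preset, ")\n", sep = "")
  for (m in names(x$coefs)) {
    cat(sprintf("  %s ~ %s; intercept %s\n", m,
                paste(sprintf("%s (%.3f)", names(x$coefs[[m]]), x$coefs[[m]]), collapse = " + "),
                if (is.na(x$intercepts[[m]])) "uncalibrated" else sprintf("%.3f", x$intercepts[[m]])))
  }
  invisible(x)
}

#' Calibrate missingness-model intercepts to target proportions
#'
#' Root-finds each indicator's logistic intercept on a large simulated
#' complete-data sample so that the realized marginal missingness
#' proportion matches its target. With all slopes zero the solution is the
#' closed form `qlogis(target)`.
#'
#' @param mechanism a [missingness_mechanism()].
#' @param model the [complete_data_model()].
#' @param targets optional override of the mechanism's target proportions
#'   (values in (0, 1)).
#' @param seed seed for the calibration sample.
#' @param n calibration sample size.
#' @return the mechanism with calibrated `intercepts`.
#' @export
calibrate_intercepts <- function(mechanism, model, targets = NULL, seed = 1L,
                                 n = 2e5) {
  if (!is.null(targets)) mechanism$targets[names(targets)] <- targets
  assert_that(all(mechanism$targets > 0 & mechanism$targets < 1),
              "targets must lie in (0, 1)")
  dat <- gen_complete(model, n, seed)
  for (m in names(mechanism$coefs)) {
    cf <- mechanism$coefs[[m]]
    lp <- linpred(dat, cf)
    tgt <- mechanism$targets[[m]]
    f <- function(b) mean(stats::plogis(b + lp)) - tgt
    lo <- -25; hi <- 25
    if (f(lo) > 0 || f(hi) < 0) {
      stop("calibration error: target ", tgt, " unattainable for ", m,
           " given its slopes", call. = FALSE)
    }
    mechanism$intercepts[[m]] <- stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
  }
  mechanism
}

#' Impose missingness on complete data under an m-DAG mechanism
#'
#' Draws the three indicators independently across records from their
#' logistic models and masks the corresponding values: `M_Z2 = 1` removes
#' the whole `Z2` block, `M_X` the exposure, `M_Y` the outcome. The latent
#' columns `L`, `U`, `W` never appear in the visible data.
#'
#' @param complete a data.frame from [gen_complete()] (must carry `W`).
#' @param mechanism a calibrated [missingness_mechanism()].
#' @param seed integer seed.
#' @param keep_complete retain the hidden complete copy (for oracle
#'   evaluation) as an attribute.
#' @return an `incomplete_data` data.frame: substantive columns with `NA`
#'   for masked values plus `M_Z2`, `M_X`, `M_Y`; attributes `schema`,
#'   `mdag_id`, `seed`, `miss_props` (realized proportions) and optionally
#'   `complete`.
#' @export
apply_missingness <- function(complete, mechanism, seed, keep_complete = TRUE) {
  assert_that(inherits(mechanism, "missingness_mechanism"), "mechanism must be a missingness_mechanism")
  assert_that(!anyNA(mechanism$intercepts), "mechanism intercepts are uncalibrated")
  sch <- attr(complete, "schema")
  assert_that(!is.null(sch), "complete data must carry a schema attribute")
  assert_that("W" %in% names(complete), "complete data must carry the latent W")
  for (m in names(mechanism$coefs)) {
    missing_cols <- setdiff(names(mechanism$coefs[[m]]), names(complete))
    assert_that(length(missing_cols) == 0,
                paste0("mechanism error: ", m, " depends on absent column(s) ",
                       paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(complete)
  M <- with_seed(seed, {
    sapply(c("M_Z2", "M_X", "M_Y"), function(m) {
      p <- stats::plogis(mechanism$intercepts[[m]] + linpred(complete, mechanism$coefs[[m]]))
      stats::rbinom(n, 1, p)
    })
  })
  M <- matrix(M, nrow = n, dimnames = list(NULL, c("M_Z2", "M_X", "M_Y")))
  vis_cols <- c(sch$z1, sch$z2, "X", "Y")
  out <- complete[vis_cols]
  out[M[, "M_Z2"] == 1, sch$z2] <- NA
  out$X[M[, "M_X"] == 1] <- NA
  out$Y[M[, "M_Y"] == 1] <- NA
  out$M_Z2 <- M[, "M_Z2"]; out$M_X <- M[, "M_X"]; out$M_Y <- M[, "M_Y"]
  structure(out,
            class = c("incomplete_data", "data.frame"),
            schema = sch,
            mdag_id = mechanism$mdag_id,
            seed = seed,
            miss_props = colMeans(M),
            complete = if (keep_complete) complete[vis_cols] else NULL)
}

#' @export
print.incomplete_data <- function(x, ...) {
  props <- attr(x, "miss_props")
  cat(sprintf("incomplete dataset: %d records (m-DAG %s); missing Z2 %.1f%%, X %.1f%%, Y %.1f%%\n",
              nrow(x), attr(x, "mdag_id") %||% "?", 100 * props[["M_Z2"]],
              100 * props[["M_X"]], 100 * props[["M_Y"]]))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Simulate an incomplete dataset under a canonical m-DAG
#'
#' Convenience wrapper: generate complete data, calibrate the missingness
#' intercepts (unless a calibrated mechanism is supplied) and impose
#' missingness.
#'
#' @param mdag_id canonical letter `"A"`-`"J"`.
#' @param n sample size.
#' @param seed integer seed.
#' @param model a [complete_data_model()]; default [cohort_model()].
#' @param mechanism optional pre-calibrated [missingness_mechanism()].
#' @param preset effect-size preset passed to [missingness_mechanism()].
#' @param keep_complete retain the hidden complete copy.
#' @return an `incomplete_data` object (see [apply_missingness()]).
#' @examples
#' d <- simulate_mdag("A", n = 500, seed = 7)
#' colMeans(is.na(d[c("X", "Y")]))
#' @export
simulate_mdag <- function(mdag_id, n, seed, model = cohort_model(), mechanism = NULL,
                          preset = "default", keep_complete = TRUE) {
  if (is.null(mechanism)) {
    mechanism <- missingness_mechanism(mdag_id, model, preset = preset)
    mechanism <- calibrate_intercepts(mechanism, model, seed = derive_seed(seed, 1L))
  }
  complete <- gen_complete(model, n, derive_seed(seed, 2L))
  apply_missingness(complete, mechanism, derive_seed(seed, 3L),
                    keep_complete = keep_complete)
}
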