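## ---- fast internal fitters -------------------------------------------------

## Logistic regression by Newton-Raphson on the log-likelihood with a small
## ridge for numerical stability. On (quasi-)separation the ridge is raised
## so the fit stays finite -- a penalized fallback, recorded in $penalized.
fit_logit <- function(X, y, weights = NULL, ridge = 1e-8, maxit = 50, start = NULL) {
  w0 <- weights %||% rep(1, length(y))
  p <- ncol(X)
  run <- function(lambda) {
    beta <- if (!is.null(start) && length(start) == p && all(is.finite(start))) start
            else numeric(p)
    for (it in seq_len(maxit)) {
      eta <- drop(X %*% beta)
      mu <- stats::plogis(eta)
      wt <- w0 * mu * (1 - mu) + 1e-12
      H <- crossprod(X, X * wt) + diag(lambda, p)
      g <- crossprod(X, w0 * (y - mu)) - lambda * beta
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      beta <- beta + drop(step)
      if (max(abs(step)) < 1e-7) break
    }
    list(beta = beta, H = crossprod(X, X * (w0 * stats::plogis(drop(X %*% beta)) *
                                              (1 - stats::plogis(drop(X %*% beta))) + 1e-12)) +
           diag(lambda, p))
  }
  fit <- run(ridge)
  penalized <- FALSE
  if (is.null(fit) || max(abs(fit$beta)) > 15) {
    fit <- run(0.05)
    penalized <- TRUE
    if (is.null(fit)) stop("estimation error: logistic fit failed", call. = FALSE)
  }
  cov <- tryCatch(chol2inv(chol(fit$H)), error = function(e) solve(fit$H + diag(1e-6, p)))
  list(beta = stats::setNames(drop(fit$beta), colnames(X)), cov = cov,
       penalized = penalized)
}

## OLS with the pieces needed for Bayesian parameter draws
fit_lm <- function(X, y) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop("estimation error: singular design", call. = FALSE)
  beta <- qr.coef(qrx, y)
  res <- y - drop(X %*% beta)
  df <- length(y) - ncol(X)
  XtXinv <- chol2inv(qr.R(qrx))
  list(beta = beta, XtXinv = XtXinv, ssr = sum(res^2), df = df,
       sigma2 = sum(res^2) / df)
}

draw_logit <- function(fit) {
  z <- stats::rnorm(length(fit$beta))
  fit$beta + drop(chol(fit$cov + diag(1e-12, length(fit$beta))) %*% z)
}

draw_lm <- function(fit) {
  sigma2 <- fit$ssr / stats::rchisq(1, fit$df)
  z <- stats::rnorm(length(fit$beta))
  beta <- fit$beta + sqrt(sigma2) * drop(chol(fit$XtXinv + diag(1e-12, length(fit$beta))) %*% z)
  list(beta = beta, sigma = sqrt(sigma2))
}

## ---- chained-equations imputation ------------------------------------------

#' Multiple imputation by chained equations
#'
#' An in-house chained-equations engine: each incomplete variable is
#' imputed from a conditional model including all other analysis variables
#' as predictors -- a Bayesian linear model with posterior and noise draws
#' for continuous variables, a logistic model with approximate posterior
#' coefficient draws for binary ones -- cycling `maxit` times per
#' imputation. Observed values are never modified. Conditional models hit
#' by separation fall back to a penalized fit (logged in the
#' `penalized_fits` attribute).
#'
#' @inheritParams available_case_mean
#' @param m number of imputations (at least 2).
#' @param maxit number of chained-equation cycles per imputation.
#' @param seed integer seed.
#' @return a list of `m` completed data.frames (class `mice_imputations`),
#'   with the schema attached.
#' @export
mice_impute <- function(data, m = 20, maxit = 10, seed = 1L, schema = NULL) {
  assert_that(m >= 2, "m must be at least 2")
  sch <- get_schema(data, schema)
  cols <- c(sch$z1, sch$z2, sch$x, sch$y)
  df <- as.data.frame(data)[cols]
  miss <- vapply(df, anyNA, TRUE)
  incomplete <- names(miss)[miss]
  for (v in incomplete) {
    assert_that(any(!is.na(df[[v]])), paste0("no observed values for ", v))
  }
  if (!length(incomplete)) {
    out <- replicate(m, df, simplify = FALSE)
    return(structure(out, class = "mice_imputations", schema = sch, penalized_fits = 0L))
  }
  binary <- vapply(df, function(v) all(stats::na.omit(v) %in% 0:1), TRUE)
  obs_idx <- lapply(df, function(v) !is.na(v))
  penalized <- 0L
  out <- with_seed(seed, {
    lapply(seq_len(m), function(imp) {
      cur <- df
      warm <- list()   # warm-start coefficients across cycles
      ## initialize by sampling observed values
      for (v in incomplete) {
        nmis <- sum(!obs_idx[[v]])
        cur[[v]][!obs_idx[[v]]] <- sample(df[[v]][obs_idx[[v]]], nmis, replace = TRUE)
      }
      for (it in seq_len(maxit)) {
        for (v in incomplete) {
          preds <- setdiff(cols, v)
          X <- cbind(1, as.matrix(cur[preds]))
          ridx <- obs_idx[[v]]
          if (binary[[v]]) {
            fit <- fit_logit(X[ridx, , drop = FALSE], df[[v]][ridx], start = warm[[v]])
            warm[[v]] <- unname(fit$beta)
            if (fit$penalized) penalized <<- penalized + 1L
            beta <- draw_logit(fit)
            pr <- stats::plogis(drop(X[!ridx, , drop = FALSE] %*% beta))
            cur[[v]][!ridx] <- stats::rbinom(sum(!ridx), 1, pr)
          } else {
            fit <- fit_lm(X[ridx, , drop = FALSE], df[[v]][ridx])
            dr <- draw_lm(fit)
            mu <- drop(X[!ridx, , drop = FALSE] %*% dr$beta)
            cur[[v]][!ridx] <- mu + stats::rnorm(sum(!ridx), sd = dr$sigma)
          }
        }
      }
      cur
    })
  })
  structure(out, class = "mice_imputations", schema = sch, penalized_fits = penalized)
}

#' @export
print.mice_imputations <- function(x, ...) {
  cat("chained-equations imputation:", length(x), "completed datasets of",
      nrow(x[[1]]), "records\n")
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Point estimate is the mean of the per-imputation estimates; total
#' variance is the within-imputation variance plus `(1 + 1/m)` times the
#' between-imputation variance; degrees of freedom follow the
#' Barnard-Rubin small-sample adjustment when a complete-data df is given.
#'
#' @param points per-imputation point estimates.
#' @param variances per-imputation squared standard errors.
#' @param df_complete complete-data degrees of freedom (`Inf` for the
#'   asymptotic rule).
#' @param parameter,method labels for the returned estimate.
#' @return a [pooled_estimate()].
#' @examples
#' rubin_pool(c(1.0, 1.2, 0.8), c(0.04, 0.04, 0.04))
#' @export
rubin_pool <- function(points, variances, df_complete = Inf,
                       parameter = "parameter", method = "mice") {
  m <- length(points)
  assert_that(m >= 2 && length(variances) == m, "need at least 2 (point, variance) pairs")
  assert_that(all(variances >= 0), "input error: negative variances")
  qbar <- mean(points)
  ubar <- mean(variances)
  b <- stats::var(points)
  t <- ubar + (1 + 1 / m) * b
  if (b == 0) {
    df <- Inf
  } else {
    r <- (1 + 1 / m) * b / ubar
    df_old <- (m - 1) * (1 + 1 / r)^2
    df <- if (is.finite(df_complete)) {
      lambda <- (1 + 1 / m) * b / t
      df_obs <- (df_complete + 1) / (df_complete + 3) * df_complete * (1 - lambda)
      1 / (1 / df_old + 1 / df_obs)
    } else df_old
  }
  pooled_estimate(parameter, qbar, sqrt(t), method, df = df, m = m)
}

## per-completed-dataset analyses of the three headline parameters
analyse_completed <- function(df, sch, parameter) {
  if (parameter == "expectation_X") {
    v <- df[[sch$x]]
    c(est = mean(v), var = stats::var(v) / length(v))
  } else if (parameter == "expectation_Y") {
    v <- df[[sch$y]]
    c(est = mean(v), var = stats::var(v) / length(v))
  } else {
    X <- cbind(1, as.matrix(df[c(sch$x, sch$z1, sch$z2)]))
    if (identical(sch$y_type, "binary")) {
      fit <- fit_logit(X, df[[sch$y]])
      c(est = fit$beta[[2]], var = fit$cov[2, 2])
    } else {
      fit <- fit_lm(X, df[[sch$y]])
      c(est = fit$beta[[2]], var = fit$sigma2 * fit$XtXinv[2, 2])
    }
  }
}

#' MICE estimate of a headline parameter
#'
#' Imputes (unless completed datasets are supplied), analyses each
#' completed dataset and pools with [rubin_pool()].
#'
#' @inheritParams mice_impute
#' @param parameter one of `expectation_X`, `expectation_Y`,
#'   `regression_coefficient`.
#' @param imputations optional result of [mice_impute()] to reuse across
#'   parameters.
#' @return a [pooled_estimate()].
#' @export
mice_estimate <- function(data, parameter = c("expectation_X", "expectation_Y",
                                              "regression_coefficient"),
                          m = 20, maxit = 10, seed = 1L, schema = NULL,
                          imputations = NULL) {
  parameter <- match.arg(parameter)
  sch <- get_schema(data, schema)
  imps <- imputations %||% mice_impute(data, m = m, maxit = maxit, seed = seed,
                                       schema = sch)
  res <- vapply(imps, analyse_completed, c(est = 0, var = 0), sch = sch,
                parameter = parameter)
  dfc <- if (parameter == "regression_coefficient") {
    nrow(imps[[1]]) - length(c(sch$x, sch$z1, sch$z2)) - 1
  } else nrow(imps[[1]]) - 1
  rubin_pool(res["est", ], res["var", ], df_complete = dfc, parameter = parameter)
}
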