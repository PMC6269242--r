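get_schema <- function(data, schema = NULL) {
  sch <- schema %||% attr(data, "schema")
  assert_that(!is.null(sch), "data carries no schema; pass one explicitly")
  sch
}

miss_col <- c(X = "M_X", Y = "M_Y")

#' Point estimate with standard error and confidence interval
#'
#' Container for a single pooled or direct estimate: the parameter, point
#' estimate, standard error, 95\% confidence interval, reference degrees of
#' freedom and a method tag (plus the imputation count for MICE).
#'
#' @param parameter parameter name.
#' @param estimate point estimate.
#' @param se standard error (may be `NA` when not computed).
#' @param method method tag.
#' @param df degrees of freedom for the t reference (`Inf` gives normal).
#' @param m imputation count (MICE only).
#' @return an object of class `pooled_estimate`.
#' @export
pooled_estimate <- function(parameter, estimate, se, method, df = Inf, m = NA_integer_) {
  assert_that(is.na(se) || se >= 0, "SE must be nonnegative")
  q <- if (is.finite(df)) stats::qt(0.975, df) else stats::qnorm(0.975)
  structure(list(parameter = parameter, estimate = estimate, se = se,
                 ci = c(lo = estimate - q * se, hi = estimate + q * se),
                 df = df, method = method, m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("%s [%s]: %.4f (SE %.4f), 95%% CI %.4f to %.4f\n",
              x$parameter, x$method, x$estimate, x$se, x$ci[["lo"]], x$ci[["hi"]]))
  invisible(x)
}

#' Available-case mean of the exposure or outcome
#'
#' Estimates the mean (for a binary variable, the proportion) using only the
#' records on which the variable is observed. Consistent only when the
#' variable is d-separated from its own missingness indicator marginally;
#' see [method_advice()].
#'
#' @param data an `incomplete_data` object (or data.frame with missingness
#'   indicator columns and a schema).
#' @param variable `"X"` or `"Y"`.
#' @param schema optional schema override.
#' @return a [pooled_estimate()].
#' @export
available_case_mean <- function(data, variable = c("X", "Y"), schema = NULL) {
  variable <- match.arg(variable)
  sch <- get_schema(data, schema)
  col <- if (variable == "X") sch$x else sch$y
  v <- data[[col]][data[[miss_col[[variable]]]] == 0]
  v <- v[!is.na(v)]
  if (length(v) < 2) stop("estimation error: fewer than 2 observed values for ", variable,
                          call. = FALSE)
  est <- mean(v)
  se <- stats::sd(v) / sqrt(length(v))
  pooled_estimate(paste0("expectation_", variable), est, se, "available_case",
                  df = length(v) - 1)
}

complete_cases <- function(data) {
  data$M_Z2 == 0 & data$M_X == 0 & data$M_Y == 0
}

#' Complete-case outcome regression
#'
#' Fits the analysis model -- linear for a continuous outcome, logistic for
#' a binary one -- of `Y` on `X`, `Z1` and `Z2` among records complete on
#' all analysis variables, and returns the coefficient of `X` with its
#' model-based standard error. Unbiased exactly when the outcome is
#' d-separated from all three missingness indicators given `(X, Z1, Z2)`,
#' which holds in canonical m-DAGs A, B, D and E.
#'
#' @inheritParams available_case_mean
#' @return a [pooled_estimate()] for `regression_coefficient`.
#' @export
complete_case_regression <- function(data, schema = NULL) {
  sch <- get_schema(data, schema)
  cc <- data[complete_cases(data), , drop = FALSE]
  covars <- c(sch$x, sch$z1, sch$z2)
  if (nrow(cc) < length(covars) + 2) {
    stop("estimation error: too few complete cases for the regression", call. = FALSE)
  }
  fml <- stats::reformulate(covars, response = sch$y)
  fit <- if (identical(sch$y_type, "binary")) {
    stats::glm(fml, data = cc, family = stats::binomial())
  } else {
    stats::lm(fml, data = cc)
  }
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop("estimation error: singular design in complete-case regression",
                      call. = FALSE)
  est <- cf[[sch$x]]
  se <- sqrt(diag(stats::vcov(fit))[[sch$x]])
  pooled_estimate("regression_coefficient", est, se, "complete_case",
                  df = if (identical(sch$y_type, "binary")) Inf else fit$df.residual)
}

is_discrete_col <- function(v, max_levels = 12) {
  u <- unique(v[!is.na(v)])
  length(u) <= max_levels && all(u == round(u))
}

#' Marginal distribution by standardization over the complete confounders
#'
#' Implements `sum_z1 P(V | Z1 = z1, M_V = 0) P(Z1 = z1)`. When all `Z1`
#' components (and `V`, for the distribution) are discrete, the stratum
#' conditionals are frequency tables; otherwise the expectation is obtained
#' by regression standardization (a main-effects model of `V` on `Z1` fitted
#' in the observed subset and averaged over the empirical `Z1`
#' distribution).
#'
#' @inheritParams available_case_mean
#' @param se_boot number of bootstrap replicates for the standard error. In
#'   discrete mode a closed-form stratified SE is available without the
#'   bootstrap; in regression mode `se_boot = 0` returns an `NA` SE.
#' @param seed seed for the bootstrap.
#' @return a list with `distribution` (a data.frame of values and
#'   probabilities, or `NULL` in regression mode) and `estimate`
#'   (a [pooled_estimate()] of the expectation).
#' @export
standardized_marginal <- function(data, variable = c("X", "Y"), schema = NULL,
                                  se_boot = 0, seed = 1L) {
  variable <- match.arg(variable)
  sch <- get_schema(data, schema)
  col <- if (variable == "X") sch$x else sch$y
  point <- function(d) {
    obs <- d[d[[miss_col[[variable]]]] == 0, , drop = FALSE]
    discrete <- all(vapply(sch$z1, function(z) is_discrete_col(d[[z]]), TRUE)) &&
      is_discrete_col(d[[col]])
    if (discrete) {
      strata_all <- interaction(d[sch$z1], drop = FALSE)
      strata_obs <- interaction(obs[sch$z1], drop = FALSE)
      wz <- table(strata_all) / nrow(d)
      vals <- sort(unique(obs[[col]]))
      p <- stats::setNames(numeric(length(vals)), vals)
      vr <- 0   # closed-form variance of the expectation, strata weights fixed
      for (st in names(wz)) {
        if (wz[[st]] == 0) next
        vs <- obs[[col]][strata_obs == st]
        if (!length(vs)) stop("empty stratum: no observed ", variable,
                              " in Z1 stratum ", st, call. = FALSE)
        tab <- table(factor(vs, levels = vals)) / length(vs)
        p <- p + wz[[st]] * as.numeric(tab)
        vr <- vr + wz[[st]]^2 * stats::var(vs) / length(vs)
      }
      list(dist = data.frame(value = vals, p = as.numeric(p)),
           est = sum(vals * p), se = sqrt(vr))
    } else {
      fml <- stats::reformulate(sch$z1, response = col)
      binary <- all(stats::na.omit(d[[col]]) %in% 0:1)
      fit <- if (binary) stats::glm(fml, data = obs, family = stats::binomial())
             else stats::lm(fml, data = obs)
      pr <- stats::predict(fit, newdata = d, type = "response")
      list(dist = NULL, est = mean(pr))
    }
  }
  pt <- point(data)
  se <- pt$se %||% NA_real_
  if (se_boot > 0) {
    boots <- with_seed(seed, {
      vapply(seq_len(se_boot), function(b) {
        idx <- sample.int(nrow(data), replace = TRUE)
        point(data[idx, , drop = FALSE])$est
      }, 1)
    })
    se <- stats::sd(boots)
  }
  list(distribution = pt$dist,
       estimate = pooled_estimate(paste0("expectation_", variable), pt$est, se,
                                  "formula_plugin"))
}

## ---- discrete joint tables -------------------------------------------------

new_discrete_joint <- function(cells, provenance) {
  cells$p <- pmax(cells$p, 0)
  cells$p <- cells$p / sum(cells$p)
  structure(cells, class = c("discrete_joint", "data.frame"), provenance = provenance)
}

#' @export
print.discrete_joint <- function(x, ...) {
  cat("discrete joint over (", paste(setdiff(names(x), "p"), collapse = ", "),
      "), ", nrow(x), " cells [", attr(x, "provenance") %||% "", "]\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}

cell_vars <- function(j) setdiff(names(j), "p")

#' Marginalize a discrete joint distribution
#' @param j a `discrete_joint`.
#' @param vars variables of the requested margin.
#' @return a `discrete_joint` over `vars`.
#' @export
dj_margin <- function(j, vars) {
  assert_that(all(vars %in% cell_vars(j)), "margin over unknown variables")
  ag <- stats::aggregate(j$p, j[vars], sum)
  names(ag)[ncol(ag)] <- "p"
  new_discrete_joint(ag, attr(j, "provenance"))
}

#' Conditional distribution from a discrete joint
#' @param j a `discrete_joint`.
#' @param of variable whose conditional distribution is requested.
#' @return a data.frame with `P(of | rest)` in column `p_cond`.
#' @export
dj_conditional <- function(j, of) {
  given <- setdiff(cell_vars(j), of)
  denom <- stats::aggregate(j$p, j[given], sum)
  names(denom)[ncol(denom)] <- "p_given"
  out <- merge(as.data.frame(j), denom, by = given)
  out$p_cond <- ifelse(out$p_given > 0, out$p / out$p_given, NA_real_)
  out
}

#' Expectation of a variable under a discrete joint
#' @param j a `discrete_joint`.
#' @param var variable name.
#' @return the expectation `sum v P(v)`.
#' @export
dj_expectation <- function(j, var) {
  m <- dj_margin(j, var)
  sum(m[[var]] * m$p)
}

#' Total-variation distance between two discrete joints
#' @param a,b `discrete_joint` tables over the same variables.
#' @return `0.5 * sum |p_a - p_b|` over the union of cells.
#' @export
tv_distance <- function(a, b) {
  vars <- cell_vars(a)
  assert_that(setequal(vars, cell_vars(b)), "joints are over different variables")
  m <- merge(as.data.frame(a), as.data.frame(b), by = vars, all = TRUE,
             suffixes = c("_a", "_b"))
  m$p_a[is.na(m$p_a)] <- 0; m$p_b[is.na(m$p_b)] <- 0
  0.5 * sum(abs(m$p_a - m$p_b))
}

#' Plug-in joint distribution under m-DAG A
#'
#' Implements `P(Y, X, Z2 | Z1, M = 0) x P(Z1)`: within each stratum of the
#' complete confounders, the complete-case joint of the remaining variables,
#' weighted by the empirical `Z1` distribution.
#'
#' @inheritParams available_case_mean
#' @return a `discrete_joint` over the `Z1`, `Z2`, `X`, `Y` columns.
#' @export
plugin_joint_A <- function(data, schema = NULL) {
  sch <- get_schema(data, schema)
  vars <- c(sch$z1, sch$z2, sch$x, sch$y)
  assert_that(all(vapply(vars, function(v) is_discrete_col(data[[v]]), TRUE)),
              "plug-in joint requires an all-discrete dataset")
  cc <- data[complete_cases(data), vars, drop = FALSE]
  strata_all <- interaction(data[sch$z1], drop = FALSE)
  strata_cc <- interaction(cc[sch$z1], drop = FALSE)
  wz <- table(strata_all) / nrow(data)
  if (any(wz > 0 & table(factor(strata_cc, levels = names(wz))) == 0)) {
    bad <- names(wz)[wz > 0 & table(factor(strata_cc, levels = names(wz))) == 0]
    stop("empty stratum: no complete cases in Z1 stratum ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  pieces <- lapply(names(wz)[wz > 0], function(st) {
    sub <- cc[strata_cc == st, , drop = FALSE]
    tab <- stats::aggregate(rep(1, nrow(sub)), sub[vars], sum)
    names(tab)[ncol(tab)] <- "p"
    tab$p <- tab$p / nrow(sub) * wz[[st]]
    tab
  })
  cells <- do.call(rbind, pieces)
  cells <- stats::aggregate(cells$p, cells[vars], sum)
  names(cells)[ncol(cells)] <- "p"
  new_discrete_joint(cells, "plug_in_joint (m-DAG A)")
}

## map graph-level variable names to data columns
graph_cols <- function(vars, sch) {
  unlist(lapply(vars, function(v) switch(v, Z1 = sch$z1, Z2 = sch$z2, X = sch$x,
                                         Y = sch$y, v)), use.names = FALSE)
}

#' Sequential inverse-probability-weighted joint distribution
#'
#' Evaluates a `sequential_ipw` identification formula: each missingness
#' factor (a conditional probability of being observed) is estimated on its
#' stated subsample -- by saturated frequencies when the conditioning
#' variables are discrete, by a main-effects logistic regression otherwise
#' -- and the records complete on the target variables are weighted by the
#' inverse product of the factors. Estimated factor probabilities are
#' truncated below at `floor` for finite-sample stability; the number of
#' truncated records is recorded in the `truncated` attribute.
#'
#' @inheritParams available_case_mean
#' @param formula an [estimand_formula()] of kind `sequential_ipw`.
#' @param floor positivity floor for estimated observation probabilities.
#' @return a `discrete_joint` over the target variables' columns.
#' @export
sequential_ipw_joint <- function(data, formula, schema = NULL, floor = 0.01) {
  assert_that(inherits(formula, "estimand_formula") && formula$kind == "sequential_ipw",
              "formula must be a sequential_ipw estimand_formula")
  sch <- get_schema(data, schema)
  tcols <- graph_cols(formula$target_vars, sch)
  need_ind <- unique(c(vapply(formula$factors, `[[`, "", "indicator")))
  keep <- rep(TRUE, nrow(data))
  for (mi in need_ind) keep <- keep & data[[mi]] == 0
  cc <- data[keep, , drop = FALSE]
  if (!nrow(cc)) stop("estimation error: no records complete on the target variables",
                      call. = FALSE)
  w <- rep(1, nrow(cc))
  truncated <- 0L
  for (f in formula$factors) {
    sub <- data
    for (mi in f$restrict) sub <- sub[sub[[mi]] == 0, , drop = FALSE]
    if (!nrow(sub)) stop("estimation error: empty fitting subsample for factor ",
                         f$indicator, call. = FALSE)
    ccols <- graph_cols(f$cond, sch)
    obs <- as.integer(sub[[f$indicator]] == 0)
    discrete <- all(vapply(ccols, function(cl) is_discrete_col(data[[cl]]), TRUE))
    if (discrete) {
      key_fit <- interaction(sub[ccols], drop = FALSE)
      tab <- tapply(obs, key_fit, mean)
      key_cc <- interaction(cc[ccols], drop = FALSE)
      pr <- as.numeric(tab[as.character(key_cc)])
      if (anyNA(pr)) stop("estimation error: complete-case cell unseen in factor ",
                          f$indicator, "'s fitting subsample", call. = FALSE)
    } else {
      fml <- stats::reformulate(ccols, response = "..obs")
      sub$..obs <- obs
      fit <- stats::glm(fml, data = sub, family = stats::binomial())
      pr <- stats::predict(fit, newdata = cc, type = "response")
    }
    truncated <- truncated + sum(pr < floor)
    pr <- pmax(pr, floor)
    w <- w / pr
  }
  cells <- stats::aggregate(w / nrow(data), cc[tcols], sum)
  names(cells)[ncol(cells)] <- "p"
  out <- new_discrete_joint(cells, paste0("sequential_ipw (", length(formula$factors),
                                          " factors)"))
  attr(out, "truncated") <- truncated
  if (truncated > 0) {
    warning("positivity warning: ", truncated,
            " record-factor probabilities truncated at ", floor, call. = FALSE)
  }
  out
}

#' Estimate a target under a canonical m-DAG's identification formula
#'
#' Looks up the recoverability verdict for `(id, target)` and, when the
#' target is recoverable, evaluates its identification formula on the data.
#'
#' @inheritParams available_case_mean
#' @param id canonical m-DAG letter.
#' @param target a verdict target (see [verdict()]).
#' @param se_boot bootstrap replicates for standardization standard errors.
#' @param seed bootstrap seed.
#' @return for distribution targets a `discrete_joint` (or conditional
#'   table); for expectation targets a [pooled_estimate()];
#'   for `regression_coefficient` the complete-case fit.
#' @export
estimate_target <- function(data, id, target, schema = NULL, se_boot = 0, seed = 1L) {
  v <- verdict(id, target)
  if (v$status != "recoverable") {
    stop("target ", target, " is not recoverable under m-DAG ", id,
         " (", v$status, "); sensitivity analysis required", call. = FALSE)
  }
  eval_formula(data, v$formula, target, schema = schema, se_boot = se_boot, seed = seed)
}

eval_formula <- function(data, formula, target, schema = NULL, se_boot = 0, seed = 1L) {
  sch <- get_schema(data, schema)
  switch(formula$kind,
    complete_case_conditional = {
      if (target == "regression_coefficient") {
        complete_case_regression(data, schema = sch)
      } else {
        vars <- c(sch$z1, sch$z2, sch$x, sch$y)
        assert_that(all(vapply(vars, function(v) is_discrete_col(data[[v]]), TRUE)),
                    "conditional table requires an all-discrete dataset")
        cc <- data[complete_cases(data), vars, drop = FALSE]
        tab <- stats::aggregate(rep(1 / nrow(cc), nrow(cc)), cc[vars], sum)
        names(tab)[ncol(tab)] <- "p"
        dj_conditional(new_discrete_joint(tab, "complete-case"), sch$y)
      }
    },
    standardize_over_Z1 = {
      out <- standardized_marginal(data, formula$var, schema = sch,
                                   se_boot = se_boot, seed = seed)
      if (startsWith(target, "expectation")) out$estimate else out
    },
    sequential_ipw = sequential_ipw_joint(data, formula, schema = sch),
    plug_in_joint = {
      j <- if (is.null(formula$base)) plugin_joint_A(data, schema = sch)
           else sequential_ipw_joint(data, formula$base, schema = sch)
      if (isTRUE(formula$conditional)) {
        if (target == "regression_coefficient") {
          joint_regression_coefficient(j, sch)
        } else dj_conditional(j, sch$y)
      } else if (!is.null(formula$margin)) {
        m <- dj_margin(j, graph_cols(formula$margin, sch))
        if (startsWith(target, "expectation")) {
          pooled_estimate(target, dj_expectation(j, graph_cols(formula$margin, sch)),
                          NA_real_, "formula_plugin")
        } else m
      } else j
    })
}

## logistic regression coefficient of X implied by a recovered discrete joint
## (all-binary mode): weighted maximum likelihood with the joint as weights.
joint_regression_coefficient <- function(j, sch) {
  vars <- cell_vars(j)
  Xm <- cbind(1, as.matrix(as.data.frame(j)[c(sch$x, sch$z1, sch$z2)]))
  y <- j[[sch$y]]
  beta <- fit_logit(Xm, y, weights = j$p)$beta
  pooled_estimate("regression_coefficient", beta[[2]], NA_real_, "formula_plugin")
}
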