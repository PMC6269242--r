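#' Identification formulas for recoverable targets
#'
#' An `estimand_formula` is a symbolic description of how a recoverable
#' distribution is expressed in terms of the available-data distribution,
#' interpretable by the plug-in estimators. Four kinds are supported:
#'
#' * `complete_case_conditional`: the conditional outcome distribution
#'   equals its complete-case version, `P(Y | X, Z1, Z2, M = 0)`.
#' * `standardize_over_Z1`: a marginal distribution recovered by
#'   standardizing the observed-subset conditional over the complete
#'   confounders, e.g. `sum_z1 P(Y | Z1 = z1, M_Y = 0) P(Z1 = z1)`.
#' * `sequential_ipw`: a joint distribution recovered by dividing the
#'   complete-case joint by a product of missingness factors, each a
#'   conditional observation probability estimated on a stated subsample.
#' * `plug_in_joint`: either the direct plug-in
#'   `P(Y, X, Z2 | Z1, M = 0) x P(Z1)` (no `base`), or a marginal /
#'   conditional functional of another recovered joint (`base` set).
#'
#' @param kind one of the four kinds above.
#' @param var for `standardize_over_Z1`: the variable being standardized.
#' @param target_vars for `sequential_ipw`: the variables of the recovered
#'   joint, e.g. `c("Z1","Z2","X","Y")`.
#' @param factors for `sequential_ipw`: list of factors, each a list with
#'   `indicator` (the missingness indicator whose observation probability
#'   the factor models), `cond` (conditioning variables) and `restrict`
#'   (indicators that must equal 0 in the fitting subsample).
#' @param base for `plug_in_joint`: an inner `sequential_ipw` formula whose
#'   recovered joint is marginalized, or `NULL` for the direct plug-in.
#' @param margin for `plug_in_joint`: variables of the requested margin
#'   (`NULL` keeps the full joint).
#' @param conditional for `plug_in_joint`: if `TRUE`, return the conditional
#'   distribution of the outcome given the remaining variables.
#' @return an object of class `estimand_formula`.
#' @export
estimand_formula <- function(kind, var = NULL, target_vars = NULL, factors = NULL,
                             base = NULL, margin = NULL, conditional = FALSE) {
  kind <- match.arg(kind, c("complete_case_conditional", "standardize_over_Z1",
                            "sequential_ipw", "plug_in_joint"))
  if (kind == "standardize_over_Z1") {
    assert_that(var %in% c("X", "Y"), "standardize_over_Z1 needs var 'X' or 'Y'")
  }
  if (kind == "sequential_ipw") {
    assert_that(!is.null(factors) && length(factors) > 0, "sequential_ipw needs factors")
    for (f in factors) {
      assert_that(all(c("indicator", "cond") %in% names(f)), "malformed factor")
      ## a conditioning variable must be observed within the stated restriction
      needs <- intersect(c("Z2", "X", "Y"), f$cond)
      guard <- c(Z2 = "M_Z2", X = "M_X", Y = "M_Y")[needs]
      assert_that(all(guard %in% (f$restrict %||% character(0))),
                  paste0("factor for ", f$indicator,
                         " conditions on a variable not observed in its restriction"))
    }
  }
  structure(list(kind = kind, var = var, target_vars = target_vars,
                 factors = factors, base = base, margin = margin,
                 conditional = conditional),
            class = "estimand_formula")
}

#' @export
format.estimand_formula <- function(x, ...) {
  switch(x$kind,
    complete_case_conditional = "P(Y | X, Z1, Z2, M = 0)",
    standardize_over_Z1 = sprintf("sum_z1 P(%s | Z1, M_%s = 0) P(Z1)", x$var, x$var),
    sequential_ipw = {
      fs <- vapply(x$factors, function(f) {
        sprintf("P(%s = 0 | %s)", f$indicator,
                paste(c(f$cond, paste0(f$restrict, " = 0")), collapse = ", "))
      }, "")
      sprintf("P(%s, M* = 0) / [%s]", paste(x$target_vars, collapse = ", "),
              paste(fs, collapse = " x "))
    },
    plug_in_joint = {
      if (is.null(x$base)) "P(Y, X, Z2 | Z1, M = 0) x P(Z1)"
      else paste0(if (isTRUE(x$conditional)) "conditional of " else
                  if (!is.null(x$margin)) paste0("margin (", paste(x$margin, collapse = ","), ") of ")
                  else "", "[", format(x$base), "]")
    })
}

#' @export
print.estimand_formula <- function(x, ...) {
  cat("identification formula [", x$kind, "]: ", format(x), "\n", sep = "")
  invisible(x)
}

seq_ipw_factor <- function(indicator, cond, restrict = character(0)) {
  list(indicator = indicator, cond = cond, restrict = restrict)
}

## the three named sequential-IPW factorizations used by the registry
seqipw_formula_B <- function() {
  estimand_formula("sequential_ipw",
    target_vars = c("Z1", "Z2", "X", "Y"),
    factors = list(
      seq_ipw_factor("M_Y", c("Z1", "Z2", "X"), c("M_Z2", "M_X")),
      seq_ipw_factor("M_Z2", c("Z1", "X"), "M_X"),
      seq_ipw_factor("M_X", c("Z1", "Z2"), "M_Z2")))
}

seqipw_formula_C <- function() {
  estimand_formula("sequential_ipw",
    target_vars = c("Z1", "Z2", "X", "Y"),
    factors = list(
      seq_ipw_factor("M_Y", c("Z1", "Z2", "X"), c("M_Z2", "M_X")),
      seq_ipw_factor("M_Z2", c("Z1", "X", "Y"), c("M_X", "M_Y")),
      seq_ipw_factor("M_X", c("Z1", "Z2", "Y"), c("M_Z2", "M_Y"))))
}

## reduced-graph factorization behind the marginal exposure distribution in
## m-DAG G: the sub-joint of (Z1, Z2, X) ignores the outcome and its
## indicator entirely.
seqipw_formula_G_reduced <- function() {
  estimand_formula("sequential_ipw",
    target_vars = c("Z1", "Z2", "X"),
    factors = list(
      seq_ipw_factor("M_Z2", c("Z1", "X"), "M_X"),
      seq_ipw_factor("M_X", c("Z1", "Z2"), "M_Z2")))
}
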