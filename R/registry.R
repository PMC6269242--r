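#' @name registry
#' @title The canonical m-DAG registry
#' @description
#' Ten canonical m-DAGs, labelled A to J, represent all essentially distinct
#' recoverability scenarios among the 16 classes of extensions of m-DAG A.
#' The registry stores, for each letter, the graph, its class signature and
#' the recoverability verdict for each target (the joint distribution, the
#' marginal exposure and outcome distributions and their expectations, the
#' conditional outcome distribution and the regression coefficient),
#' together with the identification formula where one exists.
#'
#' The canonical graphs are published as figures, not machine-readable edge
#' list, so the edge sets are transcribed from the class definitions and the
#' factorizations of the identification formulas, and then validated by the
#' package's exact-identity and Monte Carlo consistency tests. One
#' consequence of that validation is that the arrows from the latent
#' missingness cause `W` differ across letters: the sequential-IPW
#' factorizations for m-DAGs B and C (and the reduced-graph factorization
#' for G) are exact identities only when `W` does not point simultaneously
#' at the indicator pairs whose factors condition on each other's observed
#' subsample. The registry therefore carries the maximal `W` arrow set under
#' which every stated formula is exact: all three indicators for
#' A, D, E, F, H, I, J; `M_X` and `M_Y` for B and G; `M_Y` only for C.
#' See the package vignette for the derivation.
NULL

verdict_targets <- c("joint", "marginal_X", "marginal_Y", "conditional_Y",
                     "expectation_X", "expectation_Y", "regression_coefficient")

new_verdict <- function(target, status, condition = NULL, formula = NULL,
                        provenance = NULL) {
  status <- match.arg(status, c("recoverable", "nonrecoverable", "unable_conjecture_no"))
  if (!is.null(condition) && status != "unable_conjecture_no") {
    stop("conditions are attached only to unable_conjecture_no verdicts", call. = FALSE)
  }
  structure(list(target = target, status = status, condition = condition,
                 formula = formula, provenance = provenance),
            class = "verdict")
}

#' @export
print.verdict <- function(x, ...) {
  cat(sprintf("%s: %s", x$target, x$status))
  if (!is.null(x$condition)) cat(" unless ", x$condition, sep = "")
  cat("\n")
  if (!is.null(x$formula)) cat("  formula: ", format(x$formula), "\n", sep = "")
  if (!is.null(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

## letter -> (signature flags, W parents)
canonical_spec <- list(
  A = list(sig = c(0, 0, 0, 0), w = c("M_Z2", "M_X", "M_Y")),
  B = list(sig = c(1, 0, 0, 0), w = c("M_X", "M_Y")),
  C = list(sig = c(1, 0, 1, 0), w = "M_Y"),
  D = list(sig = c(0, 1, 0, 0), w = c("M_Z2", "M_X", "M_Y")),
  E = list(sig = c(1, 1, 0, 0), w = c("M_Z2", "M_X", "M_Y")),
  F = list(sig = c(0, 1, 1, 0), w = c("M_Z2", "M_X", "M_Y")),
  G = list(sig = c(1, 0, 0, 1), w = c("M_X", "M_Y")),
  H = list(sig = c(1, 0, 1, 1), w = c("M_Z2", "M_X", "M_Y")),
  I = list(sig = c(1, 1, 1, 0), w = c("M_Z2", "M_X", "M_Y")),
  J = list(sig = c(1, 1, 1, 1), w = c("M_Z2", "M_X", "M_Y")))

#' Canonical m-DAG identifiers
#' @return the letters `"A"` to `"J"`.
#' @export
canonical_ids <- function() names(canonical_spec)

cond_MY <- "M_Y _||_ {M_Z2, M_X} | {Z1, Z2, X}"
cond_MX <- "M_X _||_ {M_Z2, M_Y} | {Z1, Z2, Y}"

## provenance tags: direct_proof (direct proof), mp_corollary1 /
## mp_theorem3 / mp_corollary2 (Mohan-Pearl results), joint_recoverability
## (follows from a recovered joint, possibly of a reduced graph).
build_verdicts <- function(id) {
  ccc <- estimand_formula("complete_case_conditional")
  stdX <- estimand_formula("standardize_over_Z1", var = "X")
  stdY <- estimand_formula("standardize_over_Z1", var = "Y")
  pjA <- estimand_formula("plug_in_joint")
  mB <- function(margin = NULL, conditional = FALSE) {
    estimand_formula("plug_in_joint", base = seqipw_formula_B(), margin = margin,
                     conditional = conditional)
  }
  mC <- function(margin = NULL, conditional = FALSE) {
    estimand_formula("plug_in_joint", base = seqipw_formula_C(), margin = margin,
                     conditional = conditional)
  }
  v <- function(...) {
    out <- list(...)
    stats::setNames(out, vapply(out, function(x) x$target, ""))
  }
  rec <- function(target, formula, prov) new_verdict(target, "recoverable", formula = formula, provenance = prov)
  non <- function(target, prov) new_verdict(target, "nonrecoverable", provenance = prov)
  unable <- function(target, condition = NULL) {
    new_verdict(target, "unable_conjecture_no", condition = condition,
                provenance = "direct_proof")
  }
  switch(id,
    A = v(rec("joint", pjA, "direct_proof"),
          rec("marginal_X", stdX, "direct_proof"),
          rec("marginal_Y", stdY, "direct_proof"),
          rec("conditional_Y", ccc, "direct_proof"),
          rec("expectation_X", stdX, "direct_proof"),
          rec("expectation_Y", stdY, "direct_proof"),
          rec("regression_coefficient", ccc, "direct_proof")),
    B = v(rec("joint", seqipw_formula_B(), "mp_corollary1"),
          rec("marginal_X", mB("X"), "joint_recoverability"),
          rec("marginal_Y", mB("Y"), "joint_recoverability"),
          rec("conditional_Y", ccc, "direct_proof"),
          rec("expectation_X", mB("X"), "joint_recoverability"),
          rec("expectation_Y", mB("Y"), "joint_recoverability"),
          rec("regression_coefficient", ccc, "direct_proof")),
    C = v(rec("joint", seqipw_formula_C(), "mp_corollary1"),
          rec("marginal_X", mC("X"), "joint_recoverability"),
          rec("marginal_Y", mC("Y"), "joint_recoverability"),
          rec("conditional_Y", mC(conditional = TRUE), "joint_recoverability"),
          rec("expectation_X", mC("X"), "joint_recoverability"),
          rec("expectation_Y", mC("Y"), "joint_recoverability"),
          rec("regression_coefficient", mC(conditional = TRUE), "joint_recoverability")),
    D = v(non("joint", "mp_theorem3"),
          non("marginal_X", "mp_theorem3"),
          rec("marginal_Y", stdY, "direct_proof"),
          rec("conditional_Y", ccc, "direct_proof"),
          non("expectation_X", "mp_theorem3"),
          rec("expectation_Y", stdY, "direct_proof"),
          rec("regression_coefficient", ccc, "direct_proof")),
    E = v(non("joint", "mp_theorem3"),
          non("marginal_X", "mp_theorem3"),
          unable("marginal_Y", cond_MY),
          rec("conditional_Y", ccc, "direct_proof"),
          non("expectation_X", "mp_theorem3"),
          unable("expectation_Y", cond_MY),
          rec("regression_coefficient", ccc, "direct_proof")),
    F = v(non("joint", "mp_theorem3"),
          non("marginal_X", "mp_theorem3"),
          rec("marginal_Y", stdY, "direct_proof"),
          unable("conditional_Y"),
          non("expectation_X", "mp_theorem3"),
          rec("expectation_Y", stdY, "direct_proof"),
          unable("regression_coefficient")),
    G = v(non("joint", "mp_theorem3"),
          rec("marginal_X",
              estimand_formula("plug_in_joint", base = seqipw_formula_G_reduced(),
                               margin = "X"),
              "joint_recoverability"),
          non("marginal_Y", "mp_theorem3"),
          non("conditional_Y", "mp_corollary2"),
          rec("expectation_X",
              estimand_formula("plug_in_joint", base = seqipw_formula_G_reduced(),
                               margin = "X"),
              "joint_recoverability"),
          non("expectation_Y", "mp_theorem3"),
          non("regression_coefficient", "mp_corollary2")),
    H = v(non("joint", "mp_theorem3"),
          unable("marginal_X", cond_MX),
          non("marginal_Y", "mp_theorem3"),
          non("conditional_Y", "mp_corollary2"),
          unable("expectation_X", cond_MX),
          non("expectation_Y", "mp_theorem3"),
          non("regression_coefficient", "mp_corollary2")),
    I = v(non("joint", "mp_theorem3"),
          non("marginal_X", "mp_theorem3"),
          unable("marginal_Y", cond_MY),
          unable("conditional_Y"),
          non("expectation_X", "mp_theorem3"),
          unable("expectation_Y", cond_MY),
          unable("regression_coefficient")),
    J = v(non("joint", "mp_theorem3"),
          non("marginal_X", "mp_theorem3"),
          non("marginal_Y", "mp_theorem3"),
          non("conditional_Y", "mp_corollary2"),
          non("expectation_X", "mp_theorem3"),
          non("expectation_Y", "mp_theorem3"),
          non("regression_coefficient", "mp_corollary2")))
}

build_entry <- function(id) {
  sp <- canonical_spec[[id]]
  flags <- sp$sig
  extra <- do.call(rbind, family_edges[flags == 1L])
  g <- build_mdag(extra, w = sp$w)
  entry <- structure(
    list(id = id, mdag = g,
         signature = class_signature(flags[1], flags[2], flags[3], flags[4]),
         verdicts = build_verdicts(id),
         w_parents = sp$w,
         extra_edges = extra %||% data.frame(from = character(0), to = character(0))),
    class = "canonical_entry")
  entry
}

.registry_env <- new.env(parent = emptyenv())

registry <- function() {
  if (is.null(.registry_env$entries)) {
    .registry_env$entries <- stats::setNames(lapply(canonical_ids(), build_entry),
                                             canonical_ids())
  }
  .registry_env$entries
}

#' Look up a canonical m-DAG
#'
#' @param id one of the letters `"A"` to `"J"`.
#' @return a `canonical_entry` with elements `id`, `mdag`, `signature`,
#'   `verdicts` (one [new_verdict()] per target), `w_parents` (indicators
#'   the latent cause `W` points at) and `extra_edges` (arrows beyond
#'   m-DAG A).
#' @examples
#' canonical("A")$signature
#' canonical("E")$verdicts$marginal_Y
#' @export
canonical <- function(id) {
  id <- as.character(id)
  if (length(id) != 1L || !(id %in% canonical_ids())) {
    stop("unknown canonical m-DAG id: ", paste(id, collapse = ", "),
         " (expected one of ", paste(canonical_ids(), collapse = ", "), ")", call. = FALSE)
  }
  registry()[[id]]
}

#' @export
print.canonical_entry <- function(x, ...) {
  cat("canonical m-DAG", x$id, "with class signature", format(x$signature), "\n")
  if (nrow(x$extra_edges)) {
    cat("arrows beyond m-DAG A:",
        paste(x$extra_edges$from, "->", x$extra_edges$to, collapse = ", "), "\n")
  } else cat("no arrows beyond m-DAG A\n")
  cat("W points at:", paste(x$w_parents, collapse = ", "), "\n")
  for (v in x$verdicts[c("joint", "marginal_X", "marginal_Y", "conditional_Y")]) print(v)
  invisible(x)
}

#' Recoverability verdict for a target in a canonical m-DAG
#'
#' @param id canonical m-DAG letter, `"A"` to `"J"`.
#' @param target one of `joint`, `marginal_X`, `marginal_Y`,
#'   `conditional_Y`, `expectation_X`, `expectation_Y`,
#'   `regression_coefficient`.
#' @return a `verdict` object: status (`recoverable`, `nonrecoverable` or
#'   `unable_conjecture_no`), the conditional-independence condition under
#'   which an `unable_conjecture_no` target would be recoverable, the
#'   identification formula where one exists, and a provenance tag.
#' @examples
#' verdict("A", "joint")
#' verdict("J", "conditional_Y")
#' verdict("E", "marginal_Y")
#' @export
verdict <- function(id, target) {
  entry <- canonical(id)
  target <- match.arg(target, verdict_targets)
  entry$verdicts[[target]]
}

#' Tabulate recoverability verdicts
#'
#' @param ids canonical letters to include (default all ten).
#' @return a data.frame with one row per m-DAG and one column per target,
#'   holding the verdict statuses.
#' @export
verdict_table <- function(ids = canonical_ids()) {
  rows <- lapply(ids, function(id) {
    st <- vapply(verdict_targets, function(t) verdict(id, t)$status, "")
    cbind(data.frame(mdag = id, stringsAsFactors = FALSE),
          as.data.frame(as.list(st), stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

#' Method advice for the three headline parameters
#'
#' For each of the exposure mean, the outcome mean and the regression-
#' adjusted exposure-outcome association, reports whether the parameter is
#' recoverable under the given canonical m-DAG, whether the available-case
#' (for the association: complete-case) estimator is consistent -- decided
#' by d-separation on the graph -- whether a standard multiple-imputation
#' analysis is expected to be approximately unbiased, and, when sensitivity
#' analysis is required, the arrows responsible for nonrecoverability.
#'
#' @param id canonical m-DAG letter.
#' @return a data.frame of class `method_advice` with one row per parameter.
#' @examples
#' method_advice("A")   # all three estimable
#' method_advice("D")   # exposure mean needs sensitivity analysis (X -> M_X)
#' @export
method_advice <- function(id) {
  entry <- canonical(id)
  g <- entry$mdag
  params <- c("expectation_X", "expectation_Y", "regression_coefficient")
  rows <- lapply(params, function(p) {
    v <- entry$verdicts[[p]]
    if (p == "expectation_X") {
      ac <- d_separated(g, "X", "M_X")
      arrows <- if (has_edge(g, "X", "M_X")) "X -> M_X" else NA_character_
    } else if (p == "expectation_Y") {
      ac <- d_separated(g, "Y", "M_Y")
      arrows <- if (has_edge(g, "Y", "M_Y")) "Y -> M_Y" else NA_character_
    } else {
      ac <- d_separated(g, "Y", c("M_Z2", "M_X", "M_Y"), c("X", "Z1", "Z2"))
      arrows <- if (has_edge(g, "Y", "M_Y")) "Y -> M_Y" else NA_character_
    }
    data.frame(
      parameter = p,
      recoverability = v$status,
      available_case_consistent = ac,
      mice_expected_consistent = v$status == "recoverable",
      sensitivity_required = v$status != "recoverable",
      responsible_arrow = if (v$status == "nonrecoverable") arrows else NA_character_,
      condition = if (!is.null(v$condition)) v$condition else NA_character_,
      stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("method_advice", "data.frame"), mdag = id)
}

#' @export
print.method_advice <- function(x, ...) {
  cat("method advice for canonical m-DAG", attr(x, "mdag"), "\n")
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    cat(sprintf("- %s [%s]: %s consistent; MICE %s", r$parameter, r$recoverability,
                if (r$available_case_consistent) "available/complete-case" else "available/complete-case NOT",
                if (r$mice_expected_consistent) "expected approximately unbiased" else "not guaranteed"))
    if (isTRUE(r$sensitivity_required)) {
      cat("; sensitivity analysis required")
      if (!is.na(r$responsible_arrow)) cat(" (", r$responsible_arrow, ")", sep = "")
    }
    if (!is.na(r$condition)) cat("; recoverable only if ", r$condition, sep = "")
    cat("\n")
  }
  invisible(x)
}
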