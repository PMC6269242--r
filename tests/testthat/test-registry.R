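test_that("registry has ten valid entries with consistent signatures", {
  ids <- canonical_ids()
  expect_length(ids, 10)
  sigs <- character(0)
  for (id in ids) {
    e <- canonical(id)
    expect_equal(nrow(validate_mdag(e$mdag)), 0)
    expect_identical(unclass(classify_extension(e$mdag)), unclass(e$signature))
    sigs <- c(sigs, format(e$signature))
  }
  expect_length(unique(sigs), 10)
  all16 <- vapply(enumerate_classes(), function(e) format(e$signature), "")
  expect_true(all(sigs %in% all16))
  expect_equal(nrow(canonical("A")$extra_edges), 0)
  expect_error(canonical("K"), "unknown canonical")
})

test_that("verdict lookups match the recoverability table", {
  vA <- verdict("A", "joint")
  expect_equal(vA$status, "recoverable")
  expect_equal(vA$formula$kind, "plug_in_joint")
  expect_null(vA$formula$base)

  expect_equal(verdict("J", "conditional_Y")$status, "nonrecoverable")

  vE <- verdict("E", "marginal_Y")
  expect_equal(vE$status, "unable_conjecture_no")
  expect_match(vE$condition, "M_Y _||_ \\{M_Z2, M_X\\}")

  expect_equal(verdict("H", "marginal_X")$status, "unable_conjecture_no")
  expect_equal(verdict("D", "expectation_X")$status, "nonrecoverable")
  expect_equal(verdict("G", "marginal_X")$status, "recoverable")

  ## expectation targets inherit their distribution's status
  for (id in canonical_ids()) {
    expect_equal(verdict(id, "expectation_X")$status, verdict(id, "marginal_X")$status)
    expect_equal(verdict(id, "expectation_Y")$status, verdict(id, "marginal_Y")$status)
  }

  tab <- verdict_table()
  expect_equal(nrow(tab), 10)
  ## joint recoverable exactly when no variable causes its own missingness
  expect_setequal(tab$mdag[tab$joint == "recoverable"], c("A", "B", "C"))
})

test_that("factor conditioning sets mirror the indicator parent sets", {
  ## m-DAG B: the M_Z2 factor conditions on (Z1, X); the M_X factor on (Z1, Z2)
  fB <- verdict("B", "joint")$formula
  conds <- lapply(fB$factors, `[[`, "cond")
  names(conds) <- vapply(fB$factors, `[[`, "", "indicator")
  expect_setequal(conds$M_Z2, c("Z1", "X"))
  expect_setequal(conds$M_X, c("Z1", "Z2"))
  expect_setequal(conds$M_Y, c("Z1", "Z2", "X"))
  ## m-DAG C adds the outcome to the M_Z2 and M_X factors
  fC <- verdict("C", "joint")$formula
  condsC <- lapply(fC$factors, `[[`, "cond")
  names(condsC) <- vapply(fC$factors, `[[`, "", "indicator")
  expect_setequal(condsC$M_Z2, c("Z1", "X", "Y"))
  expect_setequal(condsC$M_X, c("Z1", "Z2", "Y"))
})

test_that("every stored identification formula is an exact identity", {
  ## population-level check on exact finite-state distributions compatible
  ## with each registry graph; identification means zero error, not just
  ## consistency
  for (id in canonical_ids()) {
    e <- canonical(id)
    for (v in e$verdicts[c("joint", "marginal_X", "marginal_Y", "conditional_Y")]) {
      if (v$status != "recoverable" || is.null(v$formula)) next
      for (ps in 1:2) {
        joint <- oracle_exact_joint(e$mdag, pars_seed = 1000 * match(id, canonical_ids()) + ps)
        err <- oracle_formula_error(v$formula, joint)
        expect_lt(err, 1e-10, label = sprintf("formula error for (%s, %s), seed %d", id, v$target, ps))
      }
    }
  }
})

test_that("'unable' verdicts correspond to genuinely failing naive formulas", {
  ## in m-DAGs E and I the standardization formula for the outcome marginal
  ## would be valid only under the stated indicator independence, which the
  ## shared latent W breaks: the formula must show real error
  stdY <- estimand_formula("standardize_over_Z1", var = "Y")
  for (id in c("E", "I")) {
    joint <- oracle_exact_joint(canonical(id)$mdag, pars_seed = 99)
    expect_gt(oracle_formula_error(stdY, joint), 1e-4)
  }
  ## and the same formula is exact in D and F, whose verdicts say recoverable
  for (id in c("D", "F")) {
    joint <- oracle_exact_joint(canonical(id)$mdag, pars_seed = 99)
    expect_lt(oracle_formula_error(stdY, joint), 1e-10)
  }
})

test_that("removing extra arrows preserves recoverable verdicts", {
  ## spot-check: dropping one extension arrow from B and C leaves the joint
  ## formula exact (recoverability is monotone under arrow removal)
  for (id in c("B", "C")) {
    e <- canonical(id)
    for (k in 1:2) {
      drop <- e$extra_edges[k, ]
      edges <- e$mdag$edges
      edges <- edges[!(edges$from == drop$from & edges$to == drop$to), ]
      g <- mdag(edges, nodes = e$mdag$nodes$name)
      joint <- oracle_exact_joint(g, pars_seed = 7 + k)
      expect_lt(oracle_formula_error(verdict(id, "joint")$formula, joint), 1e-10)
    }
  }
})

test_that("method advice names the responsible arrows", {
  aD <- method_advice("D")
  rD <- aD[aD$parameter == "expectation_X", ]
  expect_true(rD$sensitivity_required)
  expect_equal(rD$responsible_arrow, "X -> M_X")

  aA <- method_advice("A")
  expect_true(all(aA$mice_expected_consistent))
  expect_false(any(aA$sensitivity_required))

  aE <- method_advice("E")
  expect_true(aE$available_case_consistent[aE$parameter == "regression_coefficient"])
  expect_false(aE$mice_expected_consistent[aE$parameter == "expectation_X"])

  ## the complete-case association is consistent exactly in A, B, D, E
  cc_ok <- vapply(canonical_ids(), function(id) {
    a <- method_advice(id)
    a$available_case_consistent[a$parameter == "regression_coefficient"]
  }, TRUE)
  expect_setequal(names(cc_ok)[cc_ok], c("A", "B", "D", "E"))
})
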