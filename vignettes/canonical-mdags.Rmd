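---
title: "Canonical missingness DAGs: recoverability, identification and estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canonical missingness DAGs: recoverability, identification and estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(missdag)
```

## The problem

A point-exposure epidemiologic analysis estimates three things: the mean of
the exposure `X` (e.g. a prevalence), the mean of the outcome `Y`, and the
exposure-outcome association adjusted for confounders through a regression
of `Y` on `X`, the fully observed confounders `Z1` and the partially
observed confounders `Z2`. When `X`, `Y` and `Z2` all have missing values,
the classical MAR/MNAR dichotomy is a blunt instrument: "missing at random"
is hard to reason about substantively with multivariable missingness, and
many mechanisms that are technically MNAR still permit unbiased estimation
of some or all targets.

A missingness DAG (m-DAG) replaces that dichotomy with explicit structure.
The study's causal diagram is extended with one missingness indicator per
incomplete variable (`M_X = 1` when `X` is unrecorded, similarly `M_Y`;
`M_Z2` governs the whole `Z2` block, set to 1 when any component is
missing), and arrows into the indicators state *why* data are missing. A
target parameter is **recoverable** under an m-DAG if it is a function of
the distribution of the observed data, i.e. nonparametrically identified;
then some estimator is consistent for it. If it is not recoverable, no
method works without external information, and a sensitivity analysis is
the honest path.

## The canonical graphs

The complete-data diagram fixes `Z1 -> X`, `Z1 -> Y`, `Z2 -> X`, `Z2 -> Y`,
`X -> Y`, plus a latent `U -> X, Y` encoding "no unmeasured confounding
beyond U", and a latent source of dependence between `Z1` and `Z2` (used
only by the data generator, not by recoverability arguments, which never
condition between the confounder blocks). Four structural assumptions keep
the space of m-DAGs manageable: no unmeasured common causes of a
substantive variable and an indicator (so a latent `W` may drive the
indicators but nothing else, and `U` never touches the indicators); no
auxiliary variables; no arrows out of indicators; no arrows between
indicators.

The base graph, m-DAG A, lets only `Z1` (and `W`) drive missingness.
Every extension adds arrows from substantive variables to indicators, and
falls into one of 16 classes defined by four binary features:

* **f1** - confounders and/or exposure affect *other* variables' indicators;
* **f2** - confounders and/or exposure affect their *own* indicators;
* **f3** - the outcome affects *other* indicators;
* **f4** - the outcome affects its *own* indicator.

Sub-variants inside a family (only `Z2`, only `X`, or both) collapse to the
same flag, which is what caps the count at 16 (`enumerate_classes()`
materializes all of them with maximal representatives). Ten canonical
graphs A-J, each the maximal graph of its class, represent every distinct
recoverability pattern; classes not among the ten share their pattern with
a larger canonical graph. The letter-to-signature mapping used here is

```{r}
vapply(canonical_ids(), function(id) format(canonical(id)$signature), "")
```

This mapping, and the full edge sets, are a *transcription*: the canonical
framework is stated through class definitions, recoverability verdicts and
identification formulas, with the graphs drawn as figures rather than
machine-readable edge lists. We therefore
validated the transcription the only way that is airtight: every stored
identification formula must be an *exact identity* on exact finite-state
distributions generated from the transcribed graph (see
`tests/testthat/test-registry.R`), and the plug-in estimators must converge
to the truth on large simulated data.

### Where the latent W may point

That validation produced the one structurally interesting design decision
in the registry. Write the sequential-IPW factorization used for the joint
distribution under m-DAG B:

P(v) = P(v, M = 0) / [ P(M_Y=0 | Z1,Z2,X, M_Z2=0, M_X=0) x
P(M_Z2=0 | Z1,X, M_X=0) x P(M_X=0 | Z1,Z2, M_Z2=0) ]

Each factor conditions on the *other* indicator being zero whenever it
needs that variable observed (`Z2` in the `M_X` factor, `X` in the `M_Z2`
factor). If a shared latent `W` points at both `M_X` and `M_Z2`,
conditioning on one indicator opens the collider path through `W`, the
factors stop being the conditional probabilities the proof needs, and the
identity fails — provably, not approximately: a two-line counterexample
(set all substantive slopes in the indicator models to zero, keep a shared
`W` effect) makes the right-hand side differ from `P(v)` by order 1e-2.
The analogous argument shows the m-DAG C factorization tolerates at most
one `W` arrow. Meanwhile the "unable to establish / conjecture no"
verdicts in m-DAGs E, H and I are informative *only if* `W` creates
dependence between the relevant indicators: their conditions (e.g.
"recoverable unless M_Y is independent of (M_Z2, M_X) given Z1, Z2, X")
would otherwise hold trivially and the verdicts would collapse to "yes".

The registry therefore stores, per graph, the maximal `W` arrow set under
which all of its stated results are simultaneously true: `W` points at all
three indicators in A, D, E, F, H, I and J; at `M_X` and `M_Y` in B and G;
and at `M_Y` only in C. The exact-identity test suite is the arbiter for
this choice, and a Monte Carlo consistency suite (total-variation distance
below 0.01 at n = 500,000 in all-binary mode) re-confirms it end to end
through the data generator and estimators.

## Verdicts and formulas

`verdict(id, target)` returns one of three statuses. `recoverable` comes
with an identification formula: the complete-case conditional
`P(Y | X, Z1, Z2, M = 0)` (valid in A, B, D, E — exactly the graphs where
`Y` is d-separated from all indicators given `X, Z1, Z2`); standardization
over the complete confounders `sum_z1 P(V | Z1, M_V = 0) P(Z1)`; the
direct plug-in `P(Y, X, Z2 | Z1, M = 0) P(Z1)` for m-DAG A; and the
sequential-IPW factorizations for B and C (for G, a reduced-graph
factorization over `(Z1, Z2, X)` that ignores the outcome entirely
delivers the exposure margin). Where a margin has no simple expression but
the joint is recoverable, the formula marginalizes the recovered joint.
`nonrecoverable` carries a provenance tag (a general nonrecoverability
theorem applies when a variable causes its own missingness).
`unable_conjecture_no` preserves the epistemic middle ground: no proof
either way, conjectured nonrecoverable unless the stated conditional
independence between indicators holds.

Expectation targets inherit the status of their distribution, and the
regression coefficient inherits the conditional-outcome column.
`method_advice(id)` condenses this into practice: whether the
available-case mean / complete-case regression is consistent (decided by
d-separation on the graph, not by table lookup), whether standard MICE is
expected to be approximately unbiased, and which arrow is to blame when
sensitivity analysis is unavoidable.

## The synthetic-data generator

`cohort_model()` emulates a birth-cohort study of maternal mental-health
exposure and a child-behaviour score: binary exposure at 21% prevalence; a
continuous outcome with mean 7.5 and SD 3 (the scale of a 0-40
behavioural-difficulties score); one binary and one standard-normal
complete confounder; two binary incomplete confounders at roughly 20%
prevalence; latent `L` inducing confounder dependence, `U` inducing
unmeasured exposure-outcome confounding, `W` shared by the missingness
models. The structural exposure effect on the outcome is 0.6; because `U`
is unmeasured, the population coefficient of `X` in the *analysis* model
(linear in `X, Z1, Z2`) is about 1.11, and that projection — not the
structural 0.6 — is the estimand all estimators are judged against,
matching the definition "the estimate that would have been obtained had
there been no missing data". The exposure-model intercept (-2.2681) and
the outcome intercept and residual SD (6.6132, 2.5708) were calibrated
once against these targets and frozen as defaults.

Missingness mechanisms are main-effects logistic models whose support
equals the indicator's parent set in the chosen graph — interactions are
deliberately out of scope, since a DAG cannot encode them. Default slopes
are an odds ratio of 2 per unit (binary parents) or per SD (continuous
parents; the outcome's slope is divided by its SD of 3), mirroring the
magnitude of covariate-missingness associations typical of cohort studies;
the `strong` preset doubles the log odds to OR 4 and exists because the
complete-case association bias under m-DAG H only becomes material when
the outcome's effects on missingness are strong. The `W` slope is fixed at
log 2. Intercepts are never hand-set: `calibrate_intercepts()` root-finds
them on a 200,000-record simulated sample so the marginal missingness
proportions hit 19% (`Z2`), 15% (`X`) and 23% (`Y`) — the pattern of the
motivating cohort — within one percentage point.

`binary_model()` is the all-discrete counterpart (everything binary) whose
model-implied joint `true_joint()` is computed by numerical integration
over the latents, so the formula plug-ins can be checked against exact
truth rather than a simulated reference.

What the generator does **not** emulate: longitudinal attrition processes
(records are independent, one wave), interactions in either the
substantive or missingness models, auxiliary variables, and clustering.
Passing tests therefore certify the identification logic and the
estimators under main-effects mechanisms — not robustness to the messier
features of real cohort data.

## Estimation

* `available_case_mean()` uses records observed on the variable alone —
  consistent only when the variable is independent of its own indicator,
  which already fails in m-DAG A (both depend on `Z1`).
* `complete_case_regression()` fits the analysis model on fully observed
  records with model-based SEs.
* `standardized_marginal()` evaluates the standardization formula: with
  discrete `Z1` it is a frequency-table estimator with a closed-form
  stratified SE; with continuous `Z1` it standardizes a main-effects
  regression fitted in the observed subset (expectation only).
* `sequential_ipw_joint()` estimates each missingness factor on its stated
  subsample — saturated frequencies when the conditioning variables are
  discrete, main-effects logistic otherwise — and weights the complete
  cases by the inverse factor product. Estimated observation
  probabilities are floored at 0.01 (truncations counted and warned
  about): an arbitrary but conventional stability choice; the tests never
  rely on it.
* `mice_impute()` is a self-contained chained-equations engine (Bayesian
  linear draws for continuous variables, approximate-posterior logistic
  draws for binary ones, all other analysis variables as predictors —
  an approximately congenial setup), with `rubin_pool()` implementing the
  combining rules with Barnard-Rubin degrees of freedom. Separation in a
  conditional model falls back to a ridge-penalized fit rather than
  failing, with a count kept.

Numerical choices worth stating: logistic fits use Newton-Raphson with a
1e-8 ridge and a 1e-7 step tolerance (raised to a 0.05 ridge on
separation); imputation chains start from random draws of observed values;
`true_joint()` integrates on a 161-point grid per latent over [-8, 8];
the quadrature truths agree with 2-million-record simulations to three
decimals. Ties and degenerate inputs: empty `Z1` strata and all-missing
variables are errors that name the offending stratum or variable; a
mechanism whose coefficient support disagrees with the graph is rejected
before any data are touched.

## The simulation study

`run_study()` crosses canonical m-DAGs with methods and parameters at a
desk scale chosen to keep a full benchmark under a few minutes per graph:
n = 5,000 records per replicate, 500 replicates, MICE with m = 10
imputations and 5 cycles inside the loop (the standalone
`mice_impute()` defaults are m = 20 and 10 cycles). Truth is recomputed
per configuration from a single large complete-data run (n = 1,000,000 by
default); the test suite sharpens this with quadrature truths where
exactness matters. Per cell the result records truth, mean estimate, bias,
empirical SE, mean model SE, 95% CI coverage, and the Monte Carlo SE of
the bias — all pass/fail reasoning is done in MC-SE units so conclusions
do not depend on the scale of a parameter. Failed replicates are excluded
and counted; a cell with more than 5% failures is flagged as failed.
Fresh data are generated for every (graph, replicate) pair with
counter-derived seeds, so cells are independent and any run is exactly
reproducible from its config.

`qualitative_checks()` turns the study's headline patterns into explicit
booleans: available-case means suffer more than complete-case associations
under self-missingness graphs; MICE is approximately unbiased wherever the
target is recoverable; and the m-DAG H association bias grows from the
default to the strong preset. A zero-missingness control reports
"not evaluable" rather than vacuous passes.

## Worked example

```{r example}
d <- simulate_mdag("E", n = 4000, seed = 7)
method_advice("E")
complete_case_regression(d)
available_case_mean(d, "X")
```

Under m-DAG E the association is estimable from complete cases while the
exposure prevalence is not — the available-case proportion above is biased
downward, and `verdict("E", "expectation_X")` says no estimator can fix
that without external input.

## Two fine-print effects the benchmark makes visible

Two subtle, genuine phenomena show up at the benchmark's resolution
(500 replicates) and are worth naming, because they are properties of the
estimators under these study conditions, not implementation defects.

First, the complete-case regression coefficient carries a small positive
asymptotic bias (a fraction of one percent of the estimand) even in the
graphs where the conditional outcome distribution is exactly recoverable
from complete cases. The distribution-level claim is exact — the
identity tests prove it — but the *coefficient* is a least-squares
projection of a misspecified linear model: the true conditional mean
contains the nonlinear term `E[U | X, Z1, Z2]` induced by the latent
confounder the diagram mandates, and a projection under misspecification
depends on the covariate distribution, which complete-case selection
reweights. The effect is largest in m-DAG E, where the exposure feeds all
three indicators and selection on `X` is strongest. At two Monte Carlo
SEs and 500 replicates, that cell sits on the boundary.

Second, the pooled MICE interval for the exposure mean over-covers
(about 0.98 against the nominal 0.95): the chained-equations model
predicts missing exposures well, so the pooled point estimate is nearly
as efficient as the full-data mean, while Rubin's total variance still
charges the full between-imputation component. This conservativeness of
the combining rules for information-rich imputation is long documented;
it is insensitive to the number of imputations or chain length.

## Known limitations

The registry answers questions about the ten canonical graphs and their
classes; it does not decide recoverability for arbitrary user graphs
(no general algorithm exists), only class membership plus the one-way
implication "recoverable in the canonical graph implies recoverable in
every subgraph of its class". The `unable_conjecture_no` verdicts are
conjectures, reproduced as such. Mixed-mode standardization returns
expectations, not distributions. The MICE engine is deliberately minimal —
no predictive mean matching, no auxiliary variables, no multivariate
normal alternative — because its role here is to represent the standard
approximately congenial default, not to be a full imputation toolbox.
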