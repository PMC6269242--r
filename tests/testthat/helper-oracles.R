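# Independent oracles used across the suite. Everything here is written
# against first principles (path enumeration, exact probability tables) and
# never calls the package's own algorithms for the quantity being checked.

## ---- brute-force d-separation by path enumeration --------------------------

oracle_descendants <- function(edges, node) {
  seen <- node
  frontier <- node
  while (length(frontier)) {
    ch <- unique(edges$to[edges$from %in% frontier])
    frontier <- setdiff(ch, seen)
    seen <- c(seen, frontier)
  }
  seen
}

## precomputed per-graph structures: adjacency with step directions and
## descendant sets, so path enumeration is done once per node pair and
## reused across conditioning sets
oracle_cache <- function(g) {
  edges <- g$edges
  nodes <- g$nodes$name
  nbr <- lapply(stats::setNames(nodes, nodes), function(v) {
    list(node = c(edges$to[edges$from == v], edges$from[edges$to == v]),
         fwd = c(rep(TRUE, sum(edges$from == v)), rep(FALSE, sum(edges$to == v))))
  })
  desc <- lapply(stats::setNames(nodes, nodes), function(v) oracle_descendants(edges, v))
  list(nbr = nbr, desc = desc)
}

## all undirected simple paths between x and y, as lists of (node, direction)
## where direction records whether the step was along or against the arrow
oracle_paths <- function(cache, x, y) {
  out <- list()
  walk <- function(path_nodes, path_fwd) {
    v <- path_nodes[length(path_nodes)]
    if (v == y) {
      out[[length(out) + 1L]] <<- list(nodes = path_nodes, fwd = path_fwd)
      return()
    }
    nb <- cache$nbr[[v]]
    for (i in seq_along(nb$node)) {
      if (nb$node[i] %in% path_nodes) next
      walk(c(path_nodes, nb$node[i]), c(path_fwd, nb$fwd[i]))
    }
  }
  walk(x, logical(0))
  out
}

oracle_path_open <- function(path, cache, s) {
  k <- length(path$nodes)
  if (k <= 2) return(TRUE)
  for (i in 2:(k - 1)) {
    v <- path$nodes[i]
    into_v <- path$fwd[i - 1]        # previous step points into v
    out_of_v_back <- !path$fwd[i]    # next step traversed against arrow => arrow points into v
    collider <- into_v && out_of_v_back
    if (collider) {
      if (!any(cache$desc[[v]] %in% s)) return(FALSE)
    } else {
      if (v %in% s) return(FALSE)
    }
  }
  TRUE
}

oracle_dsep <- function(g, a, b, s, cache = NULL) {
  cache <- cache %||% oracle_cache(g)
  for (x in a) {
    for (y in b) {
      for (p in oracle_paths(cache, x, y)) {
        if (oracle_path_open(p, cache, s)) return(FALSE)
      }
    }
  }
  TRUE
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## shared driver: compare package d-separation with the oracle over all
## node pairs and all conditioning subsets of a random DAG; returns the
## number of agreeing checks (and fails the test on first disagreement via
## the supplied expect function)
dsep_agreement_sweep <- function(n_dags, sizes, seed, expect_fun) {
  set.seed(seed)
  n_checked <- 0
  for (rep in seq_len(n_dags)) {
    k <- sample(sizes, 1)
    g <- random_test_dag(k)
    cache <- oracle_cache(g)
    nodes <- g$nodes$name
    prs <- utils::combn(nodes, 2)
    for (ci in seq_len(ncol(prs))) {
      x <- prs[1, ci]; y <- prs[2, ci]
      paths <- oracle_paths(cache, x, y)
      rest <- setdiff(nodes, c(x, y))
      subsets <- c(list(character(0)), unlist(lapply(seq_along(rest), function(sz) {
        utils::combn(rest, sz, simplify = FALSE)
      }), recursive = FALSE))
      for (s in subsets) {
        want <- !any(vapply(paths, oracle_path_open, TRUE, cache = cache, s = s))
        got <- d_separated(g, x, y, s)
        if (!identical(got, want)) {
          expect_fun(got, want,
                     info = sprintf("disagreement: pair (%s,%s) | {%s}", x, y,
                                    paste(s, collapse = ",")))
          return(n_checked)
        }
        n_checked <- n_checked + 1
      }
    }
  }
  n_checked
}

## random DAG on k nodes: orient each selected pair along a fixed topological
## order, so acyclicity is guaranteed by construction
random_test_dag <- function(k, p = 0.35) {
  nodes <- paste0("n", seq_len(k))
  ord <- sample(nodes)
  from <- character(0); to <- character(0)
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      if (stats::runif(1) < p) {
        from <- c(from, ord[i]); to <- c(to, ord[j])
      }
    }
  }
  mdag(data.frame(from = from, to = to, stringsAsFactors = FALSE), nodes = nodes)
}

## ---- exact finite-state oracle for identification formulas -----------------

# Builds the exact joint probability table over binary
# (Z1, Z2, U, X, Y, W, M_Z2, M_X, M_Y) for an arbitrary registry graph:
# the c-DAG structure is fixed, each indicator's logistic model reads its
# parent set straight off the graph, and all coefficients are drawn
# randomly. Any distribution generated this way is compatible with the
# graph, so an identification formula must reproduce the truth exactly.

oracle_exact_joint <- function(g, pars_seed = 1) {
  set.seed(pars_seed)
  rc <- function() stats::runif(1, -1.5, 1.5)
  grid <- expand.grid(Z1 = 0:1, Z2 = 0:1, U = 0:1, X = 0:1, Y = 0:1, W = 0:1,
                      M_Z2 = 0:1, M_X = 0:1, M_Y = 0:1)
  pl <- function(x) 1 / (1 + exp(-x))
  bern <- function(val, pr) ifelse(val == 1, pr, 1 - pr)
  p <- bern(grid$Z1, 0.45) * bern(grid$U, 0.5) * bern(grid$W, 0.5) *
    bern(grid$Z2, pl(rc() + rc() * grid$Z1)) *
    bern(grid$X, pl(rc() + rc() * grid$Z1 + rc() * grid$Z2 + rc() * grid$U)) *
    bern(grid$Y, pl(rc() + rc() * grid$X + rc() * grid$Z1 + rc() * grid$Z2 + rc() * grid$U))
  for (mi in c("M_Z2", "M_X", "M_Y")) {
    pa <- g$edges$from[g$edges$to == mi]
    lp <- rep(rc(), nrow(grid))
    for (v in pa) lp <- lp + rc() * grid[[v]]
    p <- p * bern(grid[[mi]], pl(lp))
  }
  grid$p <- p / sum(p)
  grid
}

oracle_marg <- function(tab, vars, cond = NULL) {
  if (!is.null(cond)) for (v in names(cond)) tab <- tab[tab[[v]] == cond[[v]], ]
  ag <- stats::aggregate(tab$p, tab[vars], sum)
  names(ag)[ncol(ag)] <- "p"
  ag$p <- ag$p / sum(ag$p)
  ag
}

oracle_lookup <- function(tab, row) {
  for (v in setdiff(names(tab), "p")) tab <- tab[tab[[v]] == row[[v]], ]
  if (nrow(tab) == 0) 0 else tab$p
}

## P(resp = 0 | remaining columns of `row`) from a marginal table
oracle_condp0 <- function(tab, resp, row) {
  for (v in setdiff(names(tab), c("p", resp))) tab <- tab[tab[[v]] == row[[v]], ]
  tab$p[tab[[resp]] == 0] / sum(tab$p)
}

# Evaluates an estimand_formula at the population level on an exact table
# and returns the max absolute error against the corresponding truth.
oracle_formula_error <- function(formula, joint) {
  v4 <- expand.grid(Z1 = 0:1, Z2 = 0:1, X = 0:1, Y = 0:1)
  truth4 <- oracle_marg(joint, c("Z1", "Z2", "X", "Y"))
  M0 <- list(M_Z2 = 0, M_X = 0, M_Y = 0)
  if (formula$kind == "complete_case_conditional") {
    cc <- oracle_marg(joint, c("Y", "X", "Z1", "Z2"), cond = M0)
    err <- 0
    for (i in seq_len(nrow(v4))) {
      r <- v4[i, ]
      err <- max(err, abs(oracle_condp0(cc, "Y", r) - oracle_condp0(truth4, "Y", r)))
    }
    return(err)
  }
  if (formula$kind == "standardize_over_Z1") {
    v <- formula$var
    mi <- paste0("M_", v)
    cond_tab <- oracle_marg(joint, c(v, "Z1"), cond = stats::setNames(list(0), mi))
    pz1 <- oracle_marg(joint, "Z1")
    tv <- oracle_marg(joint, v)
    est0 <- sum(vapply(0:1, function(z1) {
      oracle_condp0(cond_tab, v, data.frame(Z1 = z1)) * oracle_lookup(pz1, data.frame(Z1 = z1))
    }, 1))
    return(abs(est0 - oracle_lookup(tv, stats::setNames(data.frame(0), v))))
  }
  if (formula$kind == "sequential_ipw") {
    tvars <- formula$target_vars
    inds <- vapply(formula$factors, `[[`, "", "indicator")
    condM <- stats::setNames(as.list(rep(0, length(inds))), inds)
    num <- oracle_marg(joint, tvars, cond = condM)
    pM0 <- sum(joint$p[Reduce(`&`, lapply(inds, function(mi) joint[[mi]] == 0))])
    truth <- oracle_marg(joint, tvars)
    cells <- expand.grid(stats::setNames(rep(list(0:1), length(tvars)), tvars))
    err <- 0
    for (i in seq_len(nrow(cells))) {
      r <- cells[i, , drop = FALSE]
      den <- 1
      for (f in formula$factors) {
        cond_tab <- oracle_marg(joint, c(f$indicator, f$cond),
                                cond = stats::setNames(as.list(rep(0, length(f$restrict))),
                                                       f$restrict))
        den <- den * oracle_condp0(cond_tab, f$indicator, r)
      }
      est <- oracle_lookup(num, r) * pM0 / den
      err <- max(err, abs(est - oracle_lookup(truth, r)))
    }
    return(err)
  }
  if (formula$kind == "plug_in_joint") {
    if (is.null(formula$base)) {
      cc <- oracle_marg(joint, c("Z1", "Z2", "X", "Y"), cond = M0)
      pz1 <- oracle_marg(joint, "Z1")
      err <- 0
      for (i in seq_len(nrow(v4))) {
        r <- v4[i, ]
        ccz <- cc[cc$Z1 == r$Z1, ]
        est <- oracle_lookup(cc, r) / sum(ccz$p) * oracle_lookup(pz1, r["Z1"])
        err <- max(err, abs(est - oracle_lookup(truth4, r)))
      }
      return(err)
    }
    ## marginal or conditional of a recovered joint: exactness follows from
    ## the base identity, so check the base
    return(oracle_formula_error(formula$base, joint))
  }
  stop("unknown formula kind")
}

## ---- exact population truths for the default (mixed) model -----------------

# Population values of the three headline parameters under the default
# model, by quadrature over the latents (L, U) and the continuous
# confounder's idiosyncratic noise: E[X], E[Y], and the population OLS
# coefficient of X in the linear analysis model of Y on (X, Z1, Z2)
# (the unmeasured confounder U is omitted, exactly as in the analysis).
oracle_cohort_truth <- function(model, k = 41) {
  gr <- seq(-6, 6, length.out = k)
  wq <- stats::dnorm(gr); wq <- wq / sum(wq)
  cx <- model$x$coef; cy <- model$y$coef
  combos <- expand.grid(Z1a = 0:1, Z2a = 0:1, Z2b = 0:1)
  M <- matrix(0, 6, 6); v <- numeric(6)
  for (iL in seq_len(k)) {
    L <- gr[iL]
    p1 <- stats::plogis(model$z1$Z1a$intercept + model$z1$Z1a$l * L)
    p2 <- stats::plogis(model$z2$Z2a$intercept + model$z2$Z2a$l * L)
    p3 <- stats::plogis(model$z2$Z2b$intercept + model$z2$Z2b$l * L)
    z1b <- model$z1$Z1b$l * L + model$z1$Z1b$sd * gr   # over eps grid
    for (ic in seq_len(nrow(combos))) {
      cb <- combos[ic, ]
      qc <- (if (cb$Z1a == 1) p1 else 1 - p1) * (if (cb$Z2a == 1) p2 else 1 - p2) *
        (if (cb$Z2b == 1) p3 else 1 - p3)
      base <- model$x$intercept + cx[["Z1a"]] * cb$Z1a + cx[["Z2a"]] * cb$Z2a +
        cx[["Z2b"]] * cb$Z2b
      for (ie in seq_len(k)) {
        px <- stats::plogis(base + cx[["Z1b"]] * z1b[ie] + cx[["U"]] * gr)  # over U grid
        wcell <- wq[iL] * wq[ie] * wq * qc
        wbar <- rbind(1, px, cb$Z1a, z1b[ie], cb$Z2a, cb$Z2b)   # 6 x k over U
        wW <- wbar * rep(wcell, each = 6)
        M <- M + wW %*% t(wbar)
        M[2, 2] <- M[2, 2] + sum(wcell * (px - px^2))   # E[X^2] = E[X]
        c0 <- model$y$intercept + cy[["Z1a"]] * cb$Z1a + cy[["Z1b"]] * z1b[ie] +
          cy[["Z2a"]] * cb$Z2a + cy[["Z2b"]] * cb$Z2b + cy[["U"]] * gr
        v <- v + drop(wW %*% c0) + cy[["X"]] * drop(wW %*% px)
        v[2] <- v[2] + sum(wcell * cy[["X"]] * (px - px^2))
      }
    }
  }
  beta <- solve(M, v)
  c(expectation_X = M[1, 2], expectation_Y = v[1],
    regression_coefficient = unname(beta[2]))
}
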