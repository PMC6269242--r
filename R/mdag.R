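#' Missingness DAGs for point-exposure studies
#'
#' An `mdag` is a directed graph over the substantive variables of a
#' point-exposure study -- complete confounders `Z1`, incomplete confounders
#' `Z2`, exposure `X`, outcome `Y`, the unmeasured exposure-outcome
#' confounder `U` and the unmeasured common cause of missingness `W` --
#' together with the missingness indicators `M_Z2`, `M_X`, `M_Y`
#' (`M_V = 1` when `V` is unrecorded; `M_Z2` governs the whole `Z2` block).
#' Each node carries a role; the structural assumptions that make such a
#' graph a valid missingness DAG are checked by [validate_mdag()], not by the
#' constructor, so that invalid graphs can be built and then diagnosed.
#'
#' @param edges edge specification: a two-column `data.frame` (from, to),
#'   a character vector of `"parent -> child"` strings, or a single string
#'   with one such edge per line.
#' @param roles optional named character vector mapping node names to roles
#'   (`complete_confounder`, `incomplete_confounder`, `exposure`, `outcome`,
#'   `latent_confounder_U`, `latent_missingness_cause_W`, `miss_indicator`).
#'   Roles for the standard node names are inferred when omitted; unknown
#'   node names default to `complete_confounder` so that generic DAGs can be
#'   used with [d_separated()].
#' @param nodes optional character vector of node names, to declare isolated
#'   nodes that appear in no edge.
#' @param indicator_map optional named list mapping each missingness
#'   indicator to the substantive node(s) it governs; defaults to
#'   `M_Z2 -> Z2`, `M_X -> X`, `M_Y -> Y` where those nodes exist.
#' @return an object of class `mdag`.
#' @seealso [validate_mdag()], [d_separated()], [classify_extension()],
#'   [canonical()]
#' @examples
#' g <- mdag(c("Z1 -> X", "Z1 -> Y", "X -> Y"))
#' d_separated(g, "X", "Y", "Z1")
#' @export
mdag <- function(edges = NULL, roles = NULL, nodes = NULL, indicator_map = NULL) {
  edges <- normalize_edges(edges)
  for (declared in list(nodes, names(roles))) {
    if (anyDuplicated(declared)) {
      stop("duplicate node names: ",
           paste(unique(declared[duplicated(declared)]), collapse = ", "), call. = FALSE)
    }
  }
  node_names <- unique(c(nodes, edges$from, edges$to, names(roles)))
  if (length(node_names) == 0L) stop("an mdag needs at least one node", call. = FALSE)
  if (any(!nzchar(node_names)) || anyNA(node_names)) {
    stop("empty or missing node name", call. = FALSE)
  }
  role <- infer_roles(node_names, roles)
  if (anyDuplicated(edges)) edges <- unique(edges)
  if (is.null(indicator_map)) {
    ind <- node_names[role == "miss_indicator"]
    indicator_map <- lapply(ind, function(m) {
      v <- sub("^M_", "", m)
      intersect(v, node_names)
    })
    names(indicator_map) <- ind
  }
  structure(
    list(nodes = data.frame(name = node_names, role = unname(role),
                            stringsAsFactors = FALSE),
         edges = edges,
         indicator_map = indicator_map),
    class = "mdag")
}

mdag_roles <- c("complete_confounder", "incomplete_confounder", "exposure",
                "outcome", "latent_confounder_U", "latent_missingness_cause_W",
                "miss_indicator")

default_role_map <- c(Z1 = "complete_confounder", Z2 = "incomplete_confounder",
                      X = "exposure", Y = "outcome", U = "latent_confounder_U",
                      W = "latent_missingness_cause_W",
                      M_Z2 = "miss_indicator", M_X = "miss_indicator",
                      M_Y = "miss_indicator")

infer_roles <- function(node_names, roles) {
  if (!is.null(roles)) {
    bad <- setdiff(roles, mdag_roles)
    if (length(bad)) stop("unknown node role(s): ", paste(bad, collapse = ", "), call. = FALSE)
    missing_nodes <- setdiff(names(roles), node_names)
    if (length(missing_nodes)) stop("roles given for unknown nodes: ",
                                    paste(missing_nodes, collapse = ", "), call. = FALSE)
  }
  out <- stats::setNames(rep(NA_character_, length(node_names)), node_names)
  out[names(roles)] <- roles
  inferred <- default_role_map[node_names[is.na(out)]]
  out[is.na(out)] <- ifelse(is.na(inferred), "complete_confounder", inferred)
  out
}

normalize_edges <- function(edges) {
  if (is.null(edges)) {
    return(data.frame(from = character(0), to = character(0), stringsAsFactors = FALSE))
  }
  if (is.character(edges)) {
    lines <- unlist(strsplit(edges, "\n", fixed = TRUE))
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "->", fixed = TRUE)
    bad <- lines[vapply(parts, length, 1L) != 2L]
    if (length(bad)) stop("malformed edge line(s): ", paste(bad, collapse = "; "), call. = FALSE)
    edges <- data.frame(from = trimws(vapply(parts, `[`, "", 1L)),
                        to = trimws(vapply(parts, `[`, "", 2L)),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("edges must have two columns (from, to)", call. = FALSE)
  names(edges)[1:2] <- c("from", "to")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (any(edges$from == edges$to)) stop("self-loop edge not allowed", call. = FALSE)
  edges[c("from", "to")]
}

#' @export
print.mdag <- function(x, ...) {
  cat("m-DAG with", nrow(x$nodes), "nodes and", nrow(x$edges), "edges\n")
  for (r in split(x$nodes$name, x$nodes$role)[unique(x$nodes$role)]) NULL
  roles <- split(x$nodes$name, x$nodes$role)
  for (nm in names(roles)) cat(sprintf("  %s: %s\n", nm, paste(roles[[nm]], collapse = ", ")))
  if (nrow(x$edges)) {
    cat("edges:\n")
    cat(paste0("  ", x$edges$from, " -> ", x$edges$to, collapse = "\n"), "\n")
  }
  invisible(x)
}

node_role <- function(g, nodes) {
  g$nodes$role[match(nodes, g$nodes$name)]
}

has_edge <- function(g, from, to) {
  any(g$edges$from == from & g$edges$to == to)
}

parents <- function(g, node) g$edges$from[g$edges$to == node]
children <- function(g, node) g$edges$to[g$edges$from == node]

ancestors <- function(g, nodes) {
  seen <- nodes
  frontier <- nodes
  while (length(frontier)) {
    pa <- unique(g$edges$from[g$edges$to %in% frontier])
    frontier <- setdiff(pa, seen)
    seen <- c(seen, frontier)
  }
  seen
}

descendants <- function(g, nodes) {
  seen <- nodes
  frontier <- nodes
  while (length(frontier)) {
    ch <- unique(g$edges$to[g$edges$from %in% frontier])
    frontier <- setdiff(ch, seen)
    seen <- c(seen, frontier)
  }
  seen
}

is_acyclic <- function(g) {
  ## Kahn's algorithm
  nodes <- g$nodes$name
  edges <- g$edges
  repeat {
    leaves <- setdiff(nodes, edges$from)
    if (!length(leaves)) break
    nodes <- setdiff(nodes, leaves)
    edges <- edges[!(edges$to %in% leaves), , drop = FALSE]
  }
  length(nodes) == 0L
}

#' Validate a missingness DAG against the canonical structural assumptions
#'
#' Checks the structural assumptions under which the canonical m-DAGs are
#' constructed: acyclicity; no arrows from missingness indicators to
#' substantive variables (assumption 3); no arrows between missingness
#' indicators (assumption 4); the latent missingness cause `W` has no
#' incoming arrows and points only at missingness indicators, and the latent
#' confounder `U` has no incoming arrows and points only at exposure and
#' outcome (assumption 1, which rules out unmeasured common causes of a
#' substantive variable and an indicator).
#'
#' @param g an [mdag()].
#' @return a data.frame of violations with columns `assumption` and
#'   `message`; zero rows when the graph is a valid m-DAG.
#' @examples
#' validate_mdag(canonical("A")$mdag)    # no violations
#' g <- mdag(c("M_X -> Y"))
#' validate_mdag(g)                      # assumption 3 violation
#' @export
validate_mdag <- function(g) {
  if (!inherits(g, "mdag")) stop("g must be an mdag", call. = FALSE)
  v <- list()
  add <- function(assumption, message) {
    v[[length(v) + 1L]] <<- data.frame(assumption = assumption, message = message,
                                       stringsAsFactors = FALSE)
  }
  if (!is_acyclic(g)) add("acyclicity", "graph contains a directed cycle")
  role_from <- node_role(g, g$edges$from)
  role_to <- node_role(g, g$edges$to)
  lab <- paste(g$edges$from, "->", g$edges$to)

  ind_to_sub <- role_from == "miss_indicator" & role_to != "miss_indicator"
  for (e in lab[ind_to_sub]) {
    add("assumption 3", paste0("arrow from a missingness indicator to a substantive variable: ", e))
  }
  ind_to_ind <- role_from == "miss_indicator" & role_to == "miss_indicator"
  for (e in lab[ind_to_ind]) {
    add("assumption 4", paste0("arrow between missingness indicators: ", e))
  }
  w_bad_out <- role_from == "latent_missingness_cause_W" & role_to != "miss_indicator"
  for (e in lab[w_bad_out]) {
    add("assumption 1", paste0("W may point only at missingness indicators: ", e))
  }
  w_in <- role_to == "latent_missingness_cause_W"
  for (e in lab[w_in]) add("assumption 1", paste0("W must have no incoming arrows: ", e))
  u_bad_out <- role_from == "latent_confounder_U" & !(role_to %in% c("exposure", "outcome"))
  for (e in lab[u_bad_out]) {
    add("assumption 1", paste0("U may point only at exposure and outcome: ", e))
  }
  u_in <- role_to == "latent_confounder_U"
  for (e in lab[u_in]) add("assumption 1", paste0("U must have no incoming arrows: ", e))

  if (length(v)) do.call(rbind, v) else {
    data.frame(assumption = character(0), message = character(0), stringsAsFactors = FALSE)
  }
}
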