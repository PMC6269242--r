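#' Test d-separation in a DAG
#'
#' Decides whether the node sets `a` and `b` are d-separated given `s` in
#' the directed acyclic graph `g`, by the standard ancestral-moralization
#' reduction: restrict to the ancestors of `a`, `b` and `s`; marry parents
#' of a common child; drop edge directions; delete `s`; then `a` and `b`
#' are d-separated iff no undirected path connects them.
#'
#' @param g an [mdag()] (any DAG works; roles are ignored).
#' @param a,b,s character vectors of node names; `a`, `b` and `s` must be
#'   disjoint, `s` may be empty.
#' @return `TRUE` if every path between `a` and `b` is blocked by `s`.
#' @examples
#' g <- canonical("A")$mdag
#' d_separated(g, "Y", "M_Y", "Z1")   # licenses the standardization formula
#' @export
d_separated <- function(g, a, b, s = character(0)) {
  if (!inherits(g, "mdag")) stop("g must be an mdag", call. = FALSE)
  a <- as.character(a); b <- as.character(b); s <- as.character(s)
  unknown <- setdiff(c(a, b, s), g$nodes$name)
  if (length(unknown)) stop("unknown node name(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (length(intersect(a, b)) || length(intersect(a, s)) || length(intersect(b, s))) {
    stop("a, b and s must be disjoint", call. = FALSE)
  }
  if (!length(a) || !length(b)) stop("a and b must be nonempty", call. = FALSE)
  if (!is_acyclic(g)) stop("d-separation requires an acyclic graph", call. = FALSE)

  keep <- ancestors(g, c(a, b, s))
  ed <- g$edges[g$edges$from %in% keep & g$edges$to %in% keep, , drop = FALSE]

  ## moralize: undirected adjacency on `keep`
  adj <- lapply(stats::setNames(vector("list", length(keep)), keep), function(x) character(0))
  link <- function(u, v) {
    adj[[u]] <<- c(adj[[u]], v)
    adj[[v]] <<- c(adj[[v]], u)
  }
  for (i in seq_len(nrow(ed))) link(ed$from[i], ed$to[i])
  for (child in unique(ed$to)) {
    pa <- ed$from[ed$to == child]
    if (length(pa) > 1L) {
      for (i in seq_len(length(pa) - 1L)) {
        for (j in seq.int(i + 1L, length(pa))) link(pa[i], pa[j])
      }
    }
  }

  ## delete s, then search for a path a ~> b
  avail <- setdiff(keep, s)
  visited <- intersect(a, avail)
  frontier <- visited
  target <- intersect(b, avail)
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- setdiff(intersect(nxt, avail), visited)
    if (any(nxt %in% target)) return(FALSE)
    visited <- c(visited, nxt)
    frontier <- nxt
  }
  TRUE
}
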