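## The four arrow families that classify every extension of m-DAG A:
##  f1: confounders and/or exposure -> other variables' indicators
##  f2: confounders and/or exposure -> their own indicators
##  f3: outcome -> other variables' indicators
##  f4: outcome -> its own indicator
family_edges <- list(
  f1 = data.frame(from = c("X", "X", "Z2", "Z2"),
                  to = c("M_Z2", "M_Y", "M_X", "M_Y"), stringsAsFactors = FALSE),
  f2 = data.frame(from = c("X", "Z2"), to = c("M_X", "M_Z2"), stringsAsFactors = FALSE),
  f3 = data.frame(from = c("Y", "Y"), to = c("M_Z2", "M_X"), stringsAsFactors = FALSE),
  f4 = data.frame(from = "Y", to = "M_Y", stringsAsFactors = FALSE)
)

cdag_edges <- function() {
  data.frame(from = c("Z1", "Z1", "Z2", "Z2", "X", "U", "U"),
             to = c("X", "Y", "X", "Y", "Y", "X", "Y"), stringsAsFactors = FALSE)
}

## base edges of m-DAG A: c-DAG + Z1 into every indicator + W arrows.
## w gives the indicators that W points at (all three in m-DAG A).
mdag_base_edges <- function(w = c("M_Z2", "M_X", "M_Y")) {
  ind <- c("M_Z2", "M_X", "M_Y")
  rbind(cdag_edges(),
        data.frame(from = "Z1", to = ind, stringsAsFactors = FALSE),
        if (length(w)) data.frame(from = "W", to = w, stringsAsFactors = FALSE))
}

build_mdag <- function(extra = NULL, w = c("M_Z2", "M_X", "M_Y")) {
  edges <- mdag_base_edges(w)
  if (!is.null(extra) && nrow(extra)) edges <- rbind(edges, extra)
  mdag(edges, nodes = c("Z1", "Z2", "X", "Y", "U", "W", "M_Z2", "M_X", "M_Y"))
}

#' Class signature of an extension of m-DAG A
#'
#' @param f1,f2,f3,f4 binary flags for the four arrow families: arrows from
#'   confounders/exposure to other variables' indicators (`f1`), from
#'   confounders/exposure to their own indicators (`f2`), from the outcome
#'   to other variables' indicators (`f3`), and from the outcome to its own
#'   indicator (`f4`).
#' @return an object of class `class_signature` (an integer vector of four
#'   0/1 flags).
#' @export
class_signature <- function(f1, f2, f3, f4) {
  sig <- as.integer(c(f1 = f1, f2 = f2, f3 = f3, f4 = f4))
  if (!all(sig %in% 0:1)) stop("signature flags must be 0 or 1", call. = FALSE)
  names(sig) <- c("f1", "f2", "f3", "f4")
  structure(sig, class = "class_signature")
}

#' @export
format.class_signature <- function(x, ...) {
  paste0("(", paste(unclass(x), collapse = ","), ")")
}

#' @export
print.class_signature <- function(x, ...) {
  cat("class signature", format(x), "\n")
  invisible(x)
}

#' Classify an extension of m-DAG A into one of the 16 categories
#'
#' Extensions of m-DAG A (the graph in which only the complete confounders
#' `Z1`, and the latent cause `W`, affect missingness) fall into 16
#' categories according to the presence of the four arrow families described
#' in [class_signature()]. The sub-variants within a family (e.g. only `Z2`
#' vs. only `X` pointing at another variable's indicator) collapse to the
#' same flag.
#'
#' @param g an [mdag()] that passes [validate_mdag()] and contains all base
#'   edges of m-DAG A (the c-DAG edges and `Z1` into every indicator).
#' @return a [class_signature()].
#' @examples
#' classify_extension(canonical("A")$mdag)   # (0,0,0,0)
#' classify_extension(canonical("J")$mdag)   # (1,1,1,1)
#' @export
classify_extension <- function(g) {
  viol <- validate_mdag(g)
  if (nrow(viol)) {
    stop("graph is not a valid m-DAG: ", paste(viol$message, collapse = "; "), call. = FALSE)
  }
  base <- mdag_base_edges(w = character(0))
  for (i in seq_len(nrow(base))) {
    if (!has_edge(g, base$from[i], base$to[i])) {
      stop("not an extension of m-DAG A: missing base edge ",
           base$from[i], " -> ", base$to[i], call. = FALSE)
    }
  }
  key <- function(e) paste(e$from, e$to)
  w_edges <- g$edges[node_role(g, g$edges$from) == "latent_missingness_cause_W", , drop = FALSE]
  extra <- g$edges[!(key(g$edges) %in% c(key(base), key(w_edges))), , drop = FALSE]
  allowed <- do.call(rbind, family_edges)
  stray <- extra[!(key(extra) %in% key(allowed)), , drop = FALSE]
  if (nrow(stray)) {
    stop("edge(s) outside the extension families of m-DAG A: ",
         paste(stray$from, "->", stray$to, collapse = ", "), call. = FALSE)
  }
  flags <- vapply(family_edges, function(fam) any(key(fam) %in% key(extra)), logical(1))
  class_signature(flags[1], flags[2], flags[3], flags[4])
}

#' Enumerate the 16 classes of extensions of m-DAG A
#'
#' Each class is represented by its maximal graph: the extension of m-DAG A
#' containing every arrow compatible with the class signature and the
#' structural assumptions (including `W` into every indicator).
#'
#' @return a list of 16 entries, each with elements `signature` (a
#'   [class_signature()]) and `mdag` (the maximal representative graph).
#' @examples
#' length(enumerate_classes())   # 16
#' @export
enumerate_classes <- function() {
  grid <- expand.grid(f1 = 0:1, f2 = 0:1, f3 = 0:1, f4 = 0:1)
  lapply(seq_len(nrow(grid)), function(i) {
    flags <- as.integer(grid[i, ])
    extra <- do.call(rbind, family_edges[flags == 1L])
    list(signature = class_signature(flags[1], flags[2], flags[3], flags[4]),
         mdag = build_mdag(extra))
  })
}
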