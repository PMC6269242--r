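#' Read an incomplete dataset from CSV
#'
#' Empty cells (and the token `NA`) are read as missing. The three
#' missingness indicators are derived from the data: `M_Z2 = 1` if any
#' `Z2` component is missing, `M_X` and `M_Y` if the exposure or outcome
#' is.
#'
#' @param path CSV file with a header row.
#' @param schema list with elements `z1`, `z2` (character vectors of column
#'   names), `x`, `y` (single column names) and optionally `y_type`
#'   (`"continuous"` or `"binary"`, inferred when absent).
#' @return an `incomplete_data` data.frame.
#' @export
read_incomplete_csv <- function(path, schema) {
  assert_that(all(c("z1", "z2", "x", "y") %in% names(schema)), "schema must declare z1, z2, x, y")
  raw <- utils::read.csv(path, na.strings = c("", "NA"), stringsAsFactors = FALSE,
                         check.names = FALSE)
  need <- c(schema$z1, schema$z2, schema$x, schema$y)
  absent <- setdiff(need, names(raw))
  if (length(absent)) stop("unknown column(s) in schema: ", paste(absent, collapse = ", "),
                           call. = FALSE)
  for (cl in need) {
    if (!is.numeric(raw[[cl]])) {
      conv <- suppressWarnings(as.numeric(raw[[cl]]))
      if (any(is.na(conv) & !is.na(raw[[cl]]))) {
        stop("non-numeric cell in numeric column ", cl, call. = FALSE)
      }
      raw[[cl]] <- conv
    }
  }
  if (anyNA(raw[schema$z1])) stop("Z1 columns must be completely observed", call. = FALSE)
  out <- raw[need]
  out$M_Z2 <- as.integer(rowSums(is.na(out[schema$z2])) > 0)
  out$M_X <- as.integer(is.na(out[[schema$x]]))
  out$M_Y <- as.integer(is.na(out[[schema$y]]))
  schema$y_type <- schema$y_type %||%
    (if (all(stats::na.omit(out[[schema$y]]) %in% 0:1)) "binary" else "continuous")
  structure(out, class = c("incomplete_data", "data.frame"), schema = schema,
            mdag_id = NA_character_,
            miss_props = c(M_Z2 = mean(out$M_Z2), M_X = mean(out$M_X), M_Y = mean(out$M_Y)))
}

#' Write an incomplete dataset to CSV
#'
#' Missing values are written as empty cells. An optional sidecar JSON
#' records provenance: the m-DAG id, seed and realized missingness
#' proportions.
#'
#' @param data an `incomplete_data` object.
#' @param path output CSV path.
#' @param provenance_path optional path for the provenance JSON.
#' @return `path`, invisibly.
#' @export
write_incomplete_csv <- function(data, path, provenance_path = NULL) {
  sch <- get_schema(data)
  cols <- c(sch$z1, sch$z2, sch$x, sch$y)
  utils::write.csv(as.data.frame(data)[cols], path, row.names = FALSE, na = "")
  if (!is.null(provenance_path)) {
    prov <- list(mdag_id = attr(data, "mdag_id"), seed = attr(data, "seed"),
                 n = nrow(data), miss_props = as.list(attr(data, "miss_props")),
                 schema = sch)
    jsonlite::write_json(prov, provenance_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Parse an m-DAG from a canonical letter or an edge-list file
#'
#' The edge-list format has one `parent -> child` per line; `#` starts a
#' comment; node roles may be declared in a header block of
#' `node <name> <role>` lines. The parsed graph is validated and rejected
#' (with the violated assumptions named) if it is not a valid m-DAG.
#'
#' @param x a canonical letter `"A"`-`"J"` or a file path.
#' @return an [mdag()].
#' @export
parse_mdag <- function(x) {
  if (is.character(x) && length(x) == 1 && x %in% canonical_ids()) {
    return(canonical(x)$mdag)
  }
  assert_that(file.exists(x), paste0("no such m-DAG file: ", x))
  lines <- trimws(sub("#.*$", "", readLines(x)))
  lines <- lines[nzchar(lines)]
  node_lines <- grep("^node\\s", lines, value = TRUE)
  edge_lines <- setdiff(lines, node_lines)
  roles <- NULL
  if (length(node_lines)) {
    parts <- strsplit(sub("^node\\s+", "", node_lines), "\\s+")
    bad <- node_lines[vapply(parts, length, 1L) != 2L]
    if (length(bad)) stop("malformed node line(s): ", paste(bad, collapse = "; "), call. = FALSE)
    roles <- stats::setNames(vapply(parts, `[`, "", 2L), vapply(parts, `[`, "", 1L))
  }
  g <- mdag(paste(edge_lines, collapse = "\n"), roles = roles)
  viol <- validate_mdag(g)
  if (nrow(viol)) {
    stop("invalid m-DAG (", paste(unique(viol$assumption), collapse = ", "), "): ",
         paste(viol$message, collapse = "; "), call. = FALSE)
  }
  g
}

#' Write an m-DAG as an edge-list file
#' @param g an [mdag()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mdag_edges <- function(g, path) {
  lines <- c(paste("node", g$nodes$name, g$nodes$role),
             paste(g$edges$from, "->", g$edges$to))
  writeLines(lines, path)
  invisible(path)
}

#' Export an m-DAG to Graphviz DOT
#'
#' Latent nodes are drawn dashed and missingness indicators boxed, the
#' convention used for missingness DAGs.
#'
#' @param g an [mdag()].
#' @param path optional file to write to.
#' @return the DOT source as a character scalar (invisibly when `path` is
#'   given).
#' @export
mdag_to_dot <- function(g, path = NULL) {
  style <- vapply(g$nodes$role, function(r) {
    switch(r,
           miss_indicator = " [shape=box]",
           latent_confounder_U = " [style=dashed]",
           latent_missingness_cause_W = " [style=dashed]",
           "")
  }, "")
  dot <- paste0(
    "digraph mdag {\n",
    paste0("  \"", g$nodes$name, "\"", style, ";", collapse = "\n"), "\n",
    if (nrow(g$edges)) paste0("  \"", g$edges$from, "\" -> \"", g$edges$to, "\";",
                              collapse = "\n") else "",
    "\n}\n")
  if (!is.null(path)) {
    writeLines(dot, path)
    return(invisible(dot))
  }
  dot
}
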