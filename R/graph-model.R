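# Graph and module containers, file I/O, preprocessing and node-set
# harmonization. Graphs are igraph objects: undirected, simple, vertex
# attribute `name` (unique string labels), edge attribute `weight`.

#' Build a weighted graph from an edge table
#'
#' @param edges data frame with columns `from`, `to`, `weight`.
#' @param nodes optional character vector of node labels; defaults to the
#'   labels appearing in `edges`. Extra labels become isolated nodes.
#' @return an undirected igraph object with `name` and `weight` attributes.
#' @examples
#' g <- weighted_graph(data.frame(from = "a", to = "b", weight = 1))
#' @export
weighted_graph <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges), all(c("from", "to", "weight") %in% names(edges)))
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  w <- as.numeric(edges$weight)
  if (any(from == to)) {
    stop("self-loops are not allowed: ", paste(unique(from[from == to]), collapse = ", "))
  }
  if (anyNA(w)) stop("edge weights must be real numbers")
  labels <- sort(unique(c(from, to, as.character(nodes))))
  if (length(labels) == 0L) stop("graph must contain at least one node")
  # canonical undirected key to detect duplicates
  key <- paste(pmin(from, to), pmax(from, to))
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    conflicting <- vapply(unique(dup), function(k) {
      length(unique(w[key == k])) > 1L
    }, logical(1))
    if (any(conflicting)) {
      stop("duplicate edge with conflicting weight: ",
           paste(unique(dup)[conflicting], collapse = "; "))
    }
    keep <- !duplicated(key)
    from <- from[keep]; to <- to[keep]; w <- w[keep]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = labels, stringsAsFactors = FALSE)
  )
  igraph::E(g)$weight <- w
  g
}

assert_weighted_graph <- function(g, arg = deparse(substitute(g))) {
  if (!igraph::is_igraph(g)) stop(arg, " must be an igraph object")
  if (igraph::is_directed(g)) stop(arg, " must be undirected")
  nm <- igraph::V(g)$name
  if (is.null(nm) || anyDuplicated(nm)) stop(arg, " must have unique node labels")
  if (igraph::ecount(g) > 0 && is.null(igraph::E(g)$weight)) {
    stop(arg, " must have an edge `weight` attribute")
  }
  if (igraph::any_loop(g) || igraph::any_multiple(g)) {
    stop(arg, " must be simple (no self-loops or duplicate edges)")
  }
  invisible(g)
}

#' Node modules
#'
#' A node module is an ordered set of node labels (the candidate shared
#' community S). Synthetic modules additionally record the edges of the
#' pattern planted through them.
#'
#' @param labels character vector of node labels, duplicates removed, order
#'   preserved.
#' @param planted_edges optional two-column character matrix of planted edges.
#' @return an object of class `node_module` (a character vector underneath).
#' @export
node_module <- function(labels, planted_edges = NULL) {
  labels <- as.character(labels)
  labels <- labels[!duplicated(labels)]
  if (length(labels) < 1L) stop("a node module must contain at least one label")
  structure(labels, planted_edges = planted_edges, class = "node_module")
}

#' @export
print.node_module <- function(x, ...) {
  cat("Node module with", length(x), "labels:",
      paste(head(unclass(x), 10), collapse = ", "),
      if (length(x) > 10) "..." else "", "\n")
  pe <- attr(x, "planted_edges")
  if (!is.null(pe)) cat("  planted edges:", nrow(pe), "\n")
  invisible(x)
}

module_labels <- function(S) {
  if (inherits(S, "node_module")) unclass(S) else as.character(S)
}

#' Read a weighted graph from a file
#'
#' Two formats are supported. `edgelist` is whitespace-separated
#' `label label weight` rows; lines starting with `#` are comments; each
#' undirected edge appears once. `graphml` is delegated to igraph.
#' Negative weights are preserved at read time; taking absolute values
#' ([absolute_weights()]) is a separate, explicit step.
#'
#' @param path file path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return a weighted igraph object.
#' @seealso [write_weighted_graph()]
#' @export
read_weighted_graph <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(g, mode = "each")
    assert_weighted_graph(g, arg = path)
    return(g)
  }
  lines <- readLines(path)
  # '# node <label>' directives record isolated nodes; other '#' lines are
  # comments
  iso <- sub("^\\s*#\\s*node\\s+", "", grep("^\\s*#\\s*node\\s+\\S", lines, value = TRUE))
  content <- which(!grepl("^\\s*(#|$)", lines))
  if (length(content) == 0L && length(iso) == 0L) {
    stop("empty graph rejected: ", path)
  }
  if (length(content) == 0L) {
    return(weighted_graph(data.frame(from = character(), to = character(),
                                     weight = numeric()), nodes = iso))
  }
  parts <- strsplit(trimws(lines[content]), "\\s+")
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    stop("parse error at line ", content[bad[1]], " of ", path,
         ": expected 'label label weight', got '", lines[content[bad[1]]], "'")
  }
  m <- matrix(unlist(parts), ncol = 3, byrow = TRUE)
  w <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(w)) {
    bad <- which(is.na(w))[1]
    stop("parse error at line ", content[bad], " of ", path,
         ": weight '", m[bad, 3], "' is not a number")
  }
  weighted_graph(data.frame(from = m[, 1], to = m[, 2], weight = w,
                            stringsAsFactors = FALSE),
                 nodes = iso)
}

#' Write a weighted graph to a file
#'
#' Edgelist output is canonical: one row per undirected edge, endpoints sorted
#' within the row, rows sorted lexicographically, weights printed with full
#' double precision so that a write/read round trip is exact. Isolated nodes
#' are recorded as `# node <label>` comment lines so the round trip preserves
#' the node set.
#'
#' @param g weighted igraph object.
#' @inheritParams read_weighted_graph
#' @export
write_weighted_graph <- function(g, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  assert_weighted_graph(g)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(g, names = TRUE)
  w <- igraph::E(g)$weight
  lines <- character(0)
  if (nrow(el)) {
    a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
    ord <- order(a, b)
    lines <- sprintf("%s %s %.17g", a[ord], b[ord], w[ord])
  }
  iso <- igraph::V(g)$name[igraph::degree(g) == 0]
  out <- lines
  if (length(iso)) out <- c(paste("# node", iso), out)
  writeLines(out, path)
  invisible(path)
}

#' Read / write a node module file (one label per line, '#' comments)
#'
#' @param path file path.
#' @return `read_node_module`: a [node_module()].
#' @export
read_node_module <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[!grepl("^(#|$)", lines)]
  if (!length(lines)) stop("empty module file: ", path)
  node_module(lines)
}

#' @rdname read_node_module
#' @param S a [node_module()] or character vector of labels.
#' @export
write_node_module <- function(S, path) {
  writeLines(module_labels(S), path)
  invisible(path)
}

#' Replace all edge weights by their absolute value
#'
#' Co-perturbation networks can carry negative weights (e.g. between a
#' substrate and a product around a perturbed enzyme); the sign still
#' expresses connection strength, so the magnitude is what diffusion should
#' see. Topology is unchanged.
#'
#' @param g weighted igraph object.
#' @return the same graph with `weight <- abs(weight)`.
#' @export
absolute_weights <- function(g) {
  assert_weighted_graph(g)
  if (igraph::ecount(g) > 0) igraph::E(g)$weight <- abs(igraph::E(g)$weight)
  g
}

#' Harmonize node sets by removing module nodes missing from the tester
#'
#' Module labels absent from the tester graph `g2` are dropped from the module
#' and deleted (with incident edges) from the proposer graph `g1`. This is the
#' stricter of the two harmonization strategies; it can weaken the signal but
#' never invalidates the bound.
#'
#' @param g1 proposer graph.
#' @param g2 tester graph.
#' @param S node module.
#' @return list with elements `g1` (pruned proposer) and `S` (pruned module).
#' @export
harmonize_by_removal <- function(g1, g2, S) {
  assert_weighted_graph(g1); assert_weighted_graph(g2)
  lab <- module_labels(S)
  missing <- setdiff(lab, igraph::V(g2)$name)
  kept <- setdiff(lab, missing)
  if (!length(kept)) stop("module vanishes under removal")
  if (length(missing)) {
    g1 <- igraph::delete_vertices(g1, intersect(missing, igraph::V(g1)$name))
  }
  list(g1 = g1, S = node_module(kept, planted_edges = attr(S, "planted_edges")))
}

#' Harmonize node sets by adding isolated nodes
#'
#' Both graphs are extended to the union of the two label sets; added nodes
#' are isolated (degree 0). Existing edges and weights are untouched.
#'
#' @inheritParams harmonize_by_removal
#' @return list with elements `g1` and `g2` on the common label set.
#' @export
harmonize_by_isolation <- function(g1, g2) {
  assert_weighted_graph(g1); assert_weighted_graph(g2)
  v1 <- igraph::V(g1)$name; v2 <- igraph::V(g2)$name
  add1 <- setdiff(v2, v1); add2 <- setdiff(v1, v2)
  if (length(add1)) g1 <- igraph::add_vertices(g1, length(add1), name = add1)
  if (length(add2)) g2 <- igraph::add_vertices(g2, length(add2), name = add2)
  list(g1 = g1, g2 = g2)
}
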