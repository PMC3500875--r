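#' Local independence graph
#'
#' Directed graph over named processes in which an edge `l -> k` means that
#' process `k` is locally dependent on process `l`: the local characteristic
#' (drift or intensity) of `k`, given the full past of all processes, depends
#' on the history of `l`.  Cycles are allowed -- mutual local dependence is
#' meaningful for processes -- but self-loops are not.
#'
#' @param nodes character vector of unique process names.
#' @param edges `data.frame` with columns `from` and `to` (or a 2-column
#'   matrix); duplicate edges are collapsed.
#' @param roles optional named character vector attaching a descriptive role
#'   (e.g. `"treatment"`, `"mediator"`, `"outcome"`, `"censoring"`,
#'   `"unobserved"`) to nodes.  Documentation only; roles never alter any
#'   algorithm.
#' @return An object of class `"li_graph"`.
#' @export
li_graph <- function(nodes, edges = NULL, roles = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("node names must be unique", call. = FALSE)
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (is.null(names(edges)) || !all(c("from", "to") %in% names(edges))) {
      names(edges)[1:2] <- c("from", "to")
    }
    edges <- data.frame(from = as.character(edges$from),
                        to = as.character(edges$to), stringsAsFactors = FALSE)
    bad <- setdiff(c(edges$from, edges$to), nodes)
    if (length(bad)) stop("edge endpoint(s) not in nodes: ",
                          paste(unique(bad), collapse = ", "), call. = FALSE)
    if (any(edges$from == edges$to)) {
      stop("self-loops are not allowed in a local independence graph", call. = FALSE)
    }
    edges <- unique(edges)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  if (!is.null(roles)) {
    bad <- setdiff(names(roles), nodes)
    if (length(bad)) stop("roles refer to unknown nodes: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, roles = roles),
            class = "li_graph")
}

#' @export
print.li_graph <- function(x, ...) {
  cat(sprintf("Local independence graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  cat("nodes:", paste(x$nodes, collapse = ", "), "\n")
  if (nrow(x$edges)) {
    cat("edges:", paste(sprintf("%s -> %s", x$edges$from, x$edges$to),
                        collapse = "; "), "\n")
  }
  invisible(x)
}

#' Undirected graph
#'
#' Minimal undirected-graph container used for moral graphs.  Edges are stored
#' with endpoints in canonical (sorted) order; self-loops are dropped.
#'
#' @param nodes character vector of node names.
#' @param edges `data.frame`/matrix with two columns of endpoints.
#' @return An object of class `"ugraph"`.
#' @export
ugraph <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("node names must be unique", call. = FALSE)
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- data.frame(a = character(), b = character(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    names(edges)[1:2] <- c("a", "b")
    a <- as.character(edges$a); b <- as.character(edges$b)
    bad <- setdiff(c(a, b), nodes)
    if (length(bad)) stop("edge endpoint(s) not in nodes: ",
                          paste(unique(bad), collapse = ", "), call. = FALSE)
    keep <- a != b
    lo <- pmin(a[keep], b[keep]); hi <- pmax(a[keep], b[keep])
    edges <- unique(data.frame(a = lo, b = hi, stringsAsFactors = FALSE))
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges), class = "ugraph")
}

#' @export
print.ugraph <- function(x, ...) {
  cat(sprintf("Undirected graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    cat("edges:", paste(sprintf("%s -- %s", x$edges$a, x$edges$b),
                        collapse = "; "), "\n")
  }
  invisible(x)
}

li_parents <- function(g, v) g$edges$from[g$edges$to == v]

#' Ancestral subgraph
#'
#' Induced subgraph on `keep` together with all of their ancestors, where an
#' ancestor is any node with a directed path into `keep`.  Reachability-based,
#' so defined verbatim for cyclic graphs.
#'
#' @param g a [li_graph()].
#' @param keep character vector of node names to keep.
#' @return A [li_graph()] on the ancestral closure of `keep`.
#' @export
ancestral_subgraph <- function(g, keep) {
  stopifnot(inherits(g, "li_graph"))
  keep <- resolve_nodes(keep, g$nodes, "node")
  seen <- keep
  frontier <- keep
  while (length(frontier)) {
    par <- unique(g$edges$from[g$edges$to %in% frontier])
    new <- setdiff(par, seen)
    seen <- c(seen, new)
    frontier <- new
  }
  nodes <- g$nodes[g$nodes %in% seen]
  e <- g$edges[g$edges$from %in% nodes & g$edges$to %in% nodes, , drop = FALSE]
  li_graph(nodes, e, roles = g$roles[names(g$roles) %in% nodes])
}

#' Moral graph
#'
#' Drops edge directions and "marries" the parents of every child: for each
#' node, every pair of its distinct parents is joined by an undirected edge.
#'
#' @param g a [li_graph()].
#' @return A [ugraph()] on the same nodes.
#' @export
moralize <- function(g) {
  stopifnot(inherits(g, "li_graph"))
  skel <- g$edges
  names(skel) <- c("a", "b")
  married <- lapply(g$nodes, function(v) {
    pa <- unique(li_parents(g, v))
    if (length(pa) < 2) return(NULL)
    as.data.frame(t(utils::combn(sort(pa), 2)), stringsAsFactors = FALSE)
  })
  married <- do.call(rbind, married)
  if (!is.null(married)) names(married) <- c("a", "b")
  ugraph(g$nodes, rbind(skel, married))
}

#' Test delta-separation in a local independence graph
#'
#' Decides whether, for disjoint node sets `a`, `b` and `cond`, every
#' influence route from `a` into `b` is blocked by `cond`.  The procedure is:
#' restrict to the ancestral subgraph generated by `a`, `b` and `cond`; delete
#' all directed edges starting from `b`; moralize; return whether `cond`
#' separates `a` from `b` in the resulting undirected graph.  The deletion of
#' edges out of `b` makes the criterion asymmetric in `(a, b)`, matching the
#' direction-specific nature of local independence.
#'
#' @param g a [li_graph()].
#' @param a,b nonempty, disjoint sets of node names.
#' @param cond conditioning set (possibly empty), disjoint from `a` and `b`.
#' @return Logical scalar; the moralized working graph is attached as
#'   attribute `"moral_graph"`.
#' @examples
#' g <- li_graph(c("X", "Y", "C", "L"),
#'               data.frame(from = c("X", "X", "X", "L"),
#'                          to   = c("Y", "C", "L", "Y")))
#' delta_separated(g, "C", "Y", "X")  # TRUE: all routes C <-> Y pass X
#' @export
delta_separated <- function(g, a, b, cond = character()) {
  stopifnot(inherits(g, "li_graph"))
  a <- unique(resolve_nodes(a, g$nodes, "a"))
  b <- unique(resolve_nodes(b, g$nodes, "b"))
  cond <- if (length(cond)) unique(resolve_nodes(cond, g$nodes, "cond")) else character()
  if (!length(a) || !length(b)) stop("a and b must be nonempty", call. = FALSE)
  if (length(intersect(a, b)) || length(intersect(a, cond)) ||
      length(intersect(b, cond))) {
    stop("a, b and cond must be pairwise disjoint", call. = FALSE)
  }
  anc <- ancestral_subgraph(g, c(a, b, cond))
  e <- anc$edges[!(anc$edges$from %in% b), , drop = FALSE]
  moral <- moralize(li_graph(anc$nodes, e))
  sep <- ugraph_separated(moral, a, b, cond)
  attr(sep, "moral_graph") <- moral
  sep
}

# BFS connectivity query: is every path from a to b in u blocked by cond?
ugraph_separated <- function(u, a, b, cond) {
  keep <- setdiff(u$nodes, cond)
  e <- u$edges[u$edges$a %in% keep & u$edges$b %in% keep, , drop = FALSE]
  seen <- intersect(a, keep)
  frontier <- seen
  while (length(frontier)) {
    nb <- unique(c(e$b[e$a %in% frontier], e$a[e$b %in% frontier]))
    new <- setdiff(nb, seen)
    seen <- c(seen, new)
    frontier <- new
  }
  !any(b %in% seen)
}

#' Brute-force separation check on an undirected graph
#'
#' Independent reference implementation: enumerates every simple path between
#' `a` and `b` (via `igraph::all_simple_paths`) and reports whether each one
#' passes through `cond`.  Exponential time; guarded to small graphs.  Used to
#' cross-validate the reachability check inside [delta_separated()].
#'
#' @param u a [ugraph()] (e.g. the moral graph from [delta_separated()]).
#' @param a,b,cond disjoint node sets as in [delta_separated()].
#' @param max_nodes size guard on the number of nodes.
#' @return Logical scalar.
#' @export
separation_oracle <- function(u, a, b, cond = character(), max_nodes = 10) {
  stopifnot(inherits(u, "ugraph"))
  if (length(u$nodes) > max_nodes) {
    stop(sprintf("graph has %d nodes; separation_oracle is limited to %d",
                 length(u$nodes), max_nodes), call. = FALSE)
  }
  a <- unique(as.character(a)); b <- unique(as.character(b))
  cond <- unique(as.character(cond))
  if (length(intersect(a, b)) || length(intersect(a, cond)) ||
      length(intersect(b, cond))) {
    stop("a, b and cond must be pairwise disjoint", call. = FALSE)
  }
  ig <- igraph::graph_from_data_frame(u$edges, directed = FALSE,
                                      vertices = data.frame(name = u$nodes))
  for (x in a) {
    paths <- igraph::all_simple_paths(ig, from = x, to = b, mode = "all")
    for (p in paths) {
      nm <- igraph::as_ids(p)
      inner <- nm[-c(1, length(nm))]
      if (!any(inner %in% cond)) return(FALSE)
    }
  }
  TRUE
}

#' Read or write a graph JSON file
#'
#' Schema: `{"schema": "dynpath-graph/1", "nodes": [{"name": "X", "role":
#' "treatment"}, ...], "edges": [{"from": "X", "to": "Y"}, ...]}`.  Roles are
#' optional and purely descriptive.
#'
#' @param path file path.
#' @return `read_graph_json` returns a [li_graph()].
#' @export
read_graph_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- vapply(j$nodes, function(n) if (is.list(n)) n$name else n, "")
  roles <- NULL
  if (any(vapply(j$nodes, function(n) is.list(n) && !is.null(n$role), TRUE))) {
    roles <- stats::setNames(
      vapply(j$nodes, function(n) if (is.list(n)) n$role %||% NA_character_ else NA_character_, ""),
      nodes)
    roles <- roles[!is.na(roles)]
  }
  edges <- NULL
  if (length(j$edges)) {
    edges <- data.frame(from = vapply(j$edges, `[[`, "", "from"),
                        to = vapply(j$edges, `[[`, "", "to"),
                        stringsAsFactors = FALSE)
  }
  li_graph(nodes, edges, roles = roles)
}

#' @param g a [li_graph()] to write.
#' @rdname read_graph_json
#' @export
write_graph_json <- function(g, path) {
  stopifnot(inherits(g, "li_graph"))
  nodes <- lapply(g$nodes, function(n) {
    x <- list(name = n)
    if (!is.null(g$roles) && n %in% names(g$roles)) x$role <- unname(g$roles[n])
    x
  })
  edges <- lapply(seq_len(nrow(g$edges)), function(i) {
    list(from = g$edges$from[i], to = g$edges$to[i])
  })
  jsonlite::write_json(list(schema = "dynpath-graph/1", nodes = nodes,
                            edges = edges),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
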