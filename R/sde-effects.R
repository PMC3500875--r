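#' Local-independence structure of a linear system
#'
#' Reads the local independence graph off the drift matrix: process `i` is
#' locally dependent on process `j` (edge `j -> i`) exactly when the
#' off-diagonal entry `A[i, j]` is non-zero beyond `tol`.  Diagonal entries
#' describe self-dynamics and never produce edges.
#'
#' @param model a [linear_sde()] object.
#' @param tol nonnegative threshold below which an entry counts as zero.
#' @return A [li_graph()] over the model's process labels.
#' @export
drift_to_graph <- function(model, tol = 0) {
  stopifnot(inherits(model, "linear_sde"), tol >= 0)
  A <- model$drift
  idx <- which(abs(A) > tol & row(A) != col(A), arr.ind = TRUE)
  edges <- data.frame(from = model$labels[idx[, "col"]],
                      to = model$labels[idx[, "row"]],
                      stringsAsFactors = FALSE)
  li_graph(model$labels, edges)
}

# All simple directed paths source -> target in the drift-derived graph,
# ordered lexicographically by label sequence.
enumerate_drift_paths <- function(model, source, target, max_len = Inf) {
  A <- model$drift
  labels <- model$labels
  children <- lapply(seq_along(labels), function(j) {
    ch <- which(A[, j] != 0)
    sort(labels[ch[ch != j]])
  })
  names(children) <- labels
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == target && length(path) > 1) {
      paths[[length(paths) + 1L]] <<- path
      return()
    }
    if (length(path) - 1 >= max_len) return()
    for (w in children[[v]]) {
      if (!(w %in% path)) walk(c(path, w))
    }
  }
  if (source == target) return(list())
  walk(source)
  # children are visited in sorted order, so paths arrive lexicographically
  paths
}

ancestor_labels <- function(A, labels, of) {
  # nodes with a directed path into `of` (reachability on the reversed graph)
  seen <- of
  frontier <- of
  while (length(frontier)) {
    idx <- match(frontier, labels)
    par <- labels[unique(which(A[idx, , drop = FALSE] != 0, arr.ind = TRUE)[, "col"])]
    new <- setdiff(par, seen)
    seen <- c(seen, new)
    frontier <- new
  }
  seen
}

has_cycle <- function(A) {
  # Kahn's algorithm on the off-diagonal adjacency
  diag(A) <- 0
  active <- rep(TRUE, nrow(A))
  repeat {
    indeg <- colSums(abs(A[active, active, drop = FALSE]) > 0)
    src <- which(indeg == 0)
    if (!length(src)) break
    active[which(active)[src]] <- FALSE
    if (!any(active)) break
  }
  any(active)
}

#' Split a target process by source-to-target paths
#'
#' Rebuilds the system as a tree in which the target process is replaced by
#' one copy per distinct directed path from `source` to `target`, each copy
#' receiving only the final edge of its path (shared intermediate prefixes are
#' duplicated so that every root-to-leaf route is a unique path).  This is the
#' node-splitting construction that lets a perturbation's flow be followed
#' along each individual pathway; by linearity, summing the copies recovers
#' the target's response in the original system.
#'
#' Only acyclic influence structures with zero self-dynamics along the
#' relevant paths are supported: there the number of paths is finite and the
#' per-path closed form holds.  Systems with feedback get [total_effect()]
#' only.
#'
#' @param model a [linear_sde()] object.
#' @param source,target node label or 1-based position.
#' @param max_path_len maximum number of edges per path (default: unlimited).
#' @return List with `model` (the split [linear_sde()], zero noise/input) and
#'   `registry`, a named list mapping each terminal copy's label to its path
#'   (character vector of original labels), ordered lexicographically.
#' @export
split_paths <- function(model, source, target, max_path_len = Inf) {
  stopifnot(inherits(model, "linear_sde"))
  source <- resolve_nodes(source, model$labels, "source")
  target <- resolve_nodes(target, model$labels, "target")
  A <- model$drift
  labels <- model$labels

  anc <- ancestor_labels(A, labels, target)
  sub <- match(anc, labels)
  if (has_cycle((A[sub, sub, drop = FALSE] != 0) * 1)) {
    stop("path decomposition is not defined here: the influence graph among ",
         "the target's ancestors contains a cycle (feedback); use total_effect()",
         call. = FALSE)
  }

  paths <- enumerate_drift_paths(model, source, target, max_len = max_path_len)
  if (!length(paths)) {
    stop(sprintf("no directed path from '%s' to '%s' in the influence graph",
                 source, target), call. = FALSE)
  }
  on_path <- unique(unlist(paths))
  selfd <- on_path[abs(diag(A)[match(on_path, labels)]) > 0]
  if (length(selfd)) {
    stop("path decomposition requires zero self-dynamics (zero drift diagonal) ",
         "on nodes along source-target paths; violated at: ",
         paste(selfd, collapse = ", "), call. = FALSE)
  }

  # Prefix trie over the enumerated paths: one node per distinct prefix.
  prefix_key <- function(pref) paste(pref, collapse = ".")
  prefs <- unique(unlist(lapply(paths, function(p) {
    lapply(seq_along(p), function(k) p[seq_len(k)])
  }), recursive = FALSE))
  keys <- vapply(prefs, prefix_key, "")
  pn <- length(prefs)
  A2 <- matrix(0, pn, pn, dimnames = list(keys, keys))
  for (i in seq_len(pn)) {
    pref <- prefs[[i]]
    k <- length(pref)
    if (k > 1) {
      parent <- prefix_key(pref[seq_len(k - 1)])
      A2[keys[i], parent] <- A[pref[k], pref[k - 1]]
    }
  }
  terminal <- vapply(paths, prefix_key, "")
  ord <- order(terminal)
  registry <- stats::setNames(paths[ord], terminal[ord])

  list(model = linear_sde(A2, labels = keys),
       registry = registry,
       root = source)
}

#' Path-specific effects in a linear dynamic system
#'
#' Decomposes the effect at horizon `t` of perturbing the initial level of
#' `source` by `delta` into one contribution per directed path to `target`.
#' Each contribution is read off the matrix-exponential solution of the split
#' system of [split_paths()]: the terminal copy belonging to a path receives
#' exactly the flow transmitted along that path.  For an acyclic system with
#' zero drift diagonal, a path of length \eqn{k} with edge-weight product
#' \eqn{\pi} carries effect \eqn{\pi\, t^k / k! \cdot \Delta}; in particular a
#' direct edge of weight \eqn{c} carries \eqn{c\,t\,\Delta} and a two-edge
#' path with weights \eqn{a, b} carries \eqn{a b\, t^2/2 \cdot \Delta}.  The
#' per-path effects sum to [total_effect()].
#'
#' @inheritParams split_paths
#' @param t nonnegative time horizon.
#' @param delta perturbation of the source's initial level.
#' @return A `data.frame` of class `"path_effects"` with columns `path`
#'   (label sequence joined by `" -> "`), `length` (number of edges) and
#'   `effect`; the path list and the total are attached as attributes
#'   `"paths"` and `"total"`.
#' @export
path_effects <- function(model, source, target, t, delta = 1) {
  stopifnot(inherits(model, "linear_sde"), t >= 0)
  stop_if_input(model, "path_effects()")
  split <- split_paths(model, source, target)
  m2 <- split$model
  x0 <- stats::setNames(numeric(length(m2$labels)), m2$labels)
  x0[split$root] <- delta
  es <- expected_state(m2, x0, t)
  eff <- es[names(split$registry)]
  out <- data.frame(
    path = vapply(split$registry, paste, "", collapse = " -> "),
    length = lengths(split$registry) - 1L,
    effect = unname(eff),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "paths") <- split$registry
  attr(out, "total") <- total_effect(model, source, target, t, delta)
  class(out) <- c("path_effects", "data.frame")
  out
}

#' @export
print.path_effects <- function(x, ...) {
  print.data.frame(x, ...)
  cat(sprintf("total effect: %g (sum of path effects: %g)\n",
              attr(x, "total"), sum(x$effect)))
  invisible(x)
}

#' Total effect of an initial perturbation
#'
#' The change of the expected level of `target` at horizon `t` when the
#' initial level of `source` is shifted by `delta`:
#' \eqn{(\exp(A t))_{\mathrm{target},\,\mathrm{source}} \cdot \Delta}.
#' Defined for any drift matrix, cyclic or not.
#'
#' @inheritParams path_effects
#' @return Scalar effect on the target's level.
#' @export
total_effect <- function(model, source, target, t, delta = 1) {
  stopifnot(inherits(model, "linear_sde"), t >= 0)
  stop_if_input(model, "total_effect()")
  source <- resolve_nodes(source, model$labels, "source")
  target <- resolve_nodes(target, model$labels, "target")
  E <- matexp(model$drift * t)
  dimnames(E) <- list(model$labels, model$labels)
  unname(E[target, source] * delta)
}
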