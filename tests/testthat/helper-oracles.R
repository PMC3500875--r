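# Shared fixtures and independent oracles for the test suite.

# Three-process system: 1 -> 2 (weight a), 1 -> 3 (weight c), 2 -> 3 (weight b).
# The closed-form effects of shifting process 1 by delta are c*t*delta along
# the direct edge and a*b*t^2/2*delta along the two-edge path.
chain_model <- function(a = 1, b = 1, c = 1, noise_cov = NULL) {
  A <- matrix(0, 3, 3, dimnames = list(1:3, 1:3))
  A[2, 1] <- a; A[3, 1] <- c; A[3, 2] <- b
  linear_sde(A, noise_cov = noise_cov)
}

# Treatment X, outcome Y, observed covariate L, censoring C with
# X -> Y, X -> C, X -> L, L -> Y (independent-censoring configuration:
# C has no children, and is driven only by the treatment).
censoring_graph <- function() {
  li_graph(c("X", "Y", "L", "C"),
           data.frame(from = c("X", "X", "X", "L"),
                      to   = c("Y", "C", "L", "Y")),
           roles = c(X = "treatment", Y = "outcome", L = "mediator",
                     C = "censoring"))
}

# Exposure X, mediator Z, outcome dY, unmeasured confounder U; the direct
# edge X -> dY is absent (the null being probed by the moral-graph argument).
confounded_mediator_graph <- function() {
  li_graph(c("X", "Z", "U", "dY"),
           data.frame(from = c("X", "U", "U", "Z"),
                      to   = c("Z", "Z", "dY", "dY")),
           roles = c(X = "treatment", Z = "mediator", U = "unobserved",
                     dY = "outcome"))
}

# As above but the mediator is measured before and after exposure: the
# confounder acts on the baseline value Z0 only, and Z0 feeds Zt.
repeated_mediator_graph <- function() {
  li_graph(c("X", "Z0", "Zt", "U", "dY"),
           data.frame(from = c("X", "Z0", "U", "U", "Zt"),
                      to   = c("Zt", "Zt", "Z0", "dY", "dY")),
           roles = c(X = "treatment", Z0 = "mediator", Zt = "mediator",
                     U = "unobserved", dY = "outcome"))
}

# Independent matrix-exponential oracle: truncated power series, summed until
# the term norm falls below tol with an explicit remainder guard.
expm_series <- function(M, tol = 1e-14) {
  p <- nrow(M)
  out <- diag(p)
  term <- diag(p)
  for (k in 1:200) {
    term <- term %*% M / k
    out <- out + term
    nt <- max(abs(term))
    if (nt < tol * max(1, max(abs(out))) && k > 3) break
  }
  out
}

# Independent path enumeration via igraph on the drift-derived edge set;
# returns a list of label sequences, lexicographically ordered.
enumerate_paths_oracle <- function(model, source, target) {
  A <- model$drift
  idx <- which(A != 0 & row(A) != col(A), arr.ind = TRUE)
  if (!nrow(idx)) return(list())
  ed <- data.frame(from = model$labels[idx[, "col"]],
                   to = model$labels[idx[, "row"]])
  ig <- igraph::graph_from_data_frame(ed, directed = TRUE,
                                      vertices = data.frame(name = model$labels))
  ps <- igraph::all_simple_paths(ig, from = source, to = target, mode = "out")
  ps <- lapply(ps, igraph::as_ids)
  ps[order(vapply(ps, paste, "", collapse = "\r"))]
}

# Closed-form per-path effect for acyclic zero-diagonal drift:
# (product of edge weights) * t^k / k! * delta for a path with k edges.
path_effect_oracle <- function(model, path, t, delta) {
  A <- model$drift
  w <- 1
  for (i in seq_len(length(path) - 1)) w <- w * A[path[i + 1], path[i]]
  k <- length(path) - 1
  w * t^k / factorial(k) * delta
}

# Random acyclic zero-diagonal drift matrix (p <= 6, weights in [-2, 2]) with
# at least one path from node "1" to node "p"; labels follow a random
# topological order so edge direction is not tied to index order.
random_acyclic_model <- function(p = sample(3:6, 1), edge_prob = 0.5) {
  ord <- sample(p)
  A <- matrix(0, p, p)
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    if (stats::runif(1) < edge_prob) {
      A[ord[j], ord[i]] <- stats::runif(1, -2, 2)
    }
  }
  if (A[ord[p], ord[1]] == 0) A[ord[p], ord[1]] <- stats::runif(1, -2, 2)
  m <- linear_sde(A, labels = as.character(seq_len(p)))
  list(model = m, source = as.character(ord[1]), target = as.character(ord[p]))
}

# Random directed graph for separation cross-validation.
random_li_graph <- function(max_nodes = 8, edge_prob = 0.25) {
  p <- sample(4:max_nodes, 1)
  nodes <- as.character(seq_len(p))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs <- pairs[stats::runif(nrow(pairs)) < edge_prob, , drop = FALSE]
  li_graph(nodes, pairs)
}

# Random disjoint (a, b, cond) triple from a node set.
random_abc <- function(nodes) {
  p <- length(nodes)
  ncond <- sample(0:(p - 2), 1)
  pick <- sample(nodes, 2 + ncond)
  list(a = pick[1], b = pick[2],
       cond = if (ncond > 0) pick[-(1:2)] else character())
}

# Small deterministic counting-process dataset used across dpa tests.
hand_dataset <- function() {
  read_counting_process_csv(system.file("extdata", "hand8.csv",
                                        package = "dynpath"))
}
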