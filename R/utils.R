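# Internal numerical helpers shared across modules.

# Least squares with an explicit rank check: returns NULL on rank deficiency
# instead of falling back to a generalized inverse, so callers can skip-and-log.
ols_solve <- function(X, y) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) return(NULL)
  XtX <- crossprod(X)
  coef <- drop(solve(XtX, crossprod(X, y)))
  list(coef = coef, XtX_inv = solve(XtX), qr = qx)
}

# Symmetric PSD square root via eigendecomposition; eigenvalues below -tol
# are a validation error, small negatives are clamped to zero.
psd_sqrt <- function(S, tol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  if (any(e$values < -tol * max(1, abs(e$values[1L])))) {
    stop("noise covariance is not positive semi-definite", call. = FALSE)
  }
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

# Matrix exponential (scaling-and-squaring, via the Matrix package).
matexp <- function(M) {
  if (!is.matrix(M)) M <- as.matrix(M)
  unname(as.matrix(Matrix::expm(Matrix::Matrix(M, sparse = FALSE))))
}

# Resolve node references given by label or 1-based position to labels.
resolve_nodes <- function(ref, labels, arg = "node") {
  if (is.numeric(ref)) {
    if (any(ref < 1 | ref > length(labels) | ref != round(ref))) {
      stop(sprintf("invalid %s position(s): %s", arg,
                   paste(ref[ref < 1 | ref > length(labels)], collapse = ", ")),
           call. = FALSE)
    }
    return(labels[ref])
  }
  ref <- as.character(ref)
  bad <- setdiff(ref, labels)
  if (length(bad)) {
    stop(sprintf("unknown %s: %s", arg, paste(bad, collapse = ", ")), call. = FALSE)
  }
  ref
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Column-wise cumulative sums that stay a matrix even with one row.
col_cumsum <- function(m) {
  out <- apply(m, 2, cumsum)
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(m), ncol = ncol(m),
                                     dimnames = dimnames(m))
  out
}
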