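#' Fit an additive hazard model by least-squares increments
#'
#' Nonparametric additive (Aalen) hazard fit: at every event time \eqn{t_k}
#' the vector of coefficient increments \eqn{d\hat B(t_k)} solves the ordinary
#' least-squares problem of the event-indicator vector on the at-risk design
#' matrix, and the increments are summed into cumulative regression functions
#' \eqn{\hat B(t)}.  Tied event times are processed as a single time with a
#' multi-event indicator vector.  At-risk means `start < t <= stop`; covariate
#' values are the interval values (step functions, last observation carried
#' forward).
#'
#' Rank-deficient designs at a given event time are skipped and logged -- no
#' silent generalized inverse -- so the cumulative curves remain sums of
#' well-defined least-squares increments.  The per-increment covariance is the
#' least-squares form \eqn{X^- \,\mathrm{diag}(dN)\, (X^-)'} with
#' \eqn{X^- = (X'X)^{-1} X'}, accumulated over time for the cumulative curves.
#'
#' @param data a [counting_process_data()] object (or coercible data.frame).
#' @param regressors character vector of covariate column names (possibly
#'   empty for an intercept-only fit, which reproduces the occurrence/exposure
#'   cumulative-hazard step estimator with increments \eqn{d_k / r_k}).
#' @param intercept include an intercept column (default `TRUE`).
#' @return An object of class `"addhaz"`: list with `times`, `increments` and
#'   `cumulative` (K x p matrices), `var_increments` / `var_cumulative`
#'   (coefficient variances), `at_risk`, `n_events`, `skipped_times` and
#'   `terms`.
#' @references Aalen-type least-squares estimation of cumulative regression
#'   functions in the additive hazard model.
#' @export
fit_additive_hazard <- function(data, regressors = character(), intercept = TRUE) {
  if (!inherits(data, "cpdata")) data <- counting_process_data(data)
  if (!intercept && !length(regressors)) {
    stop("need an intercept or at least one regressor", call. = FALSE)
  }
  miss <- setdiff(regressors, names(data))
  if (length(miss)) stop("regressor(s) not in data: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  ev_times <- sort(unique(data$stop[data$event == 1L]))
  if (!length(ev_times)) stop("no events in the data", call. = FALSE)

  terms <- c(if (intercept) "(Intercept)", regressors)
  p <- length(terms)
  K <- length(ev_times)
  inc <- matrix(NA_real_, K, p, dimnames = list(NULL, terms))
  vinc <- matrix(NA_real_, K, p, dimnames = list(NULL, terms))
  r_k <- integer(K); d_k <- integer(K)
  ok <- logical(K)

  for (k in seq_len(K)) {
    tk <- ev_times[k]
    idx <- at_risk_index(data, tk)
    r_k[k] <- sum(idx)
    dN <- as.numeric(data$stop[idx] == tk & data$event[idx] == 1L)
    d_k[k] <- sum(dN)
    X <- cbind(if (intercept) rep(1, r_k[k]),
               if (length(regressors)) as.matrix(data[idx, regressors, drop = FALSE]))
    colnames(X) <- terms
    if (nrow(X) < p) next
    fit <- ols_solve(X, dN)
    if (is.null(fit)) next
    ok[k] <- TRUE
    inc[k, ] <- fit$coef
    Xm <- fit$XtX_inv %*% t(X)            # X^-
    W <- Xm[, dN == 1, drop = FALSE]
    vinc[k, ] <- diag(tcrossprod(W))
  }
  skipped <- ev_times[!ok]
  if (length(skipped)) {
    warning(sprintf("%d of %d event times skipped (rank-deficient design)",
                    length(skipped), K), call. = FALSE)
  }
  times <- ev_times[ok]
  inc <- inc[ok, , drop = FALSE]
  vinc <- vinc[ok, , drop = FALSE]
  structure(
    list(times = times,
         increments = inc,
         cumulative = col_cumsum(inc),
         var_increments = vinc,
         var_cumulative = col_cumsum(vinc),
         at_risk = r_k[ok],
         n_events = d_k[ok],
         skipped_times = skipped,
         terms = terms),
    class = "addhaz"
  )
}

#' @export
print.addhaz <- function(x, ...) {
  cat(sprintf("Additive hazard fit: %d event times, terms: %s\n",
              length(x$times), paste(x$terms, collapse = ", ")))
  if (length(x$skipped_times)) {
    cat(sprintf("skipped %d event time(s) with rank-deficient design\n",
                length(x$skipped_times)))
  }
  cat("Cumulative regression functions at the last event time:\n")
  print(x$cumulative[length(x$times), ])
  invisible(x)
}

#' Long-format view of an additive hazard fit
#'
#' @param x an `"addhaz"` object.
#' @param ... unused.
#' @return `data.frame` with columns `time`, `term`, `coefficient`
#'   (increment), `cumulative`, `variance` (of the cumulative), `at_risk`.
#' @export
as.data.frame.addhaz <- function(x, ...) {
  K <- length(x$times)
  data.frame(
    time = rep(x$times, times = length(x$terms)),
    term = rep(x$terms, each = K),
    coefficient = as.vector(x$increments),
    cumulative = as.vector(x$cumulative),
    variance = as.vector(x$var_cumulative),
    at_risk = rep(x$at_risk, times = length(x$terms)),
    stringsAsFactors = FALSE
  )
}

#' Per-event-time mediator regressions
#'
#' Ordinary least squares of a covariate's current (carried-forward) value on
#' a set of regressors plus intercept, over the at-risk set at each requested
#' time -- the "standard linear regression for each jump time" half of dynamic
#' path analysis.
#'
#' @param data a [counting_process_data()] object.
#' @param mediator name of the covariate used as response.
#' @param regressors names of covariates used as predictors.
#' @param at_times times at which to run the regressions (typically the event
#'   times of an additive hazard fit).
#' @return Object of class `"mediator_series"`: list with `times`, `coef` and
#'   `se` matrices (columns `(Intercept)` then regressors), `n` (at-risk
#'   counts) and `skipped_times`.
#' @export
fit_mediator_series <- function(data, mediator, regressors = character(),
                                at_times) {
  if (!inherits(data, "cpdata")) data <- counting_process_data(data)
  if (!length(at_times)) stop("at_times must be nonempty", call. = FALSE)
  miss <- setdiff(c(mediator, regressors), names(data))
  if (length(miss)) stop("column(s) not in data: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  at_times <- sort(unique(as.numeric(at_times)))
  terms <- c("(Intercept)", regressors)
  p <- length(terms)
  K <- length(at_times)
  coef <- matrix(NA_real_, K, p, dimnames = list(NULL, terms))
  se <- matrix(NA_real_, K, p, dimnames = list(NULL, terms))
  n <- integer(K)
  ok <- logical(K)
  for (k in seq_len(K)) {
    tk <- at_times[k]
    idx <- at_risk_index(data, tk)
    n[k] <- sum(idx)
    if (n[k] < p) next
    y <- data[[mediator]][idx]
    X <- cbind(rep(1, n[k]),
               if (length(regressors)) as.matrix(data[idx, regressors, drop = FALSE]))
    colnames(X) <- terms
    fit <- ols_solve(X, y)
    if (is.null(fit)) next
    ok[k] <- TRUE
    coef[k, ] <- fit$coef
    res <- y - drop(X %*% fit$coef)
    s2 <- if (n[k] > p) sum(res^2) / (n[k] - p) else NA_real_
    se[k, ] <- sqrt(s2 * diag(fit$XtX_inv))
  }
  structure(
    list(times = at_times[ok],
         coef = coef[ok, , drop = FALSE],
         se = se[ok, , drop = FALSE],
         n = n[ok],
         skipped_times = at_times[!ok],
         mediator = mediator, terms = terms),
    class = "mediator_series"
  )
}

#' @export
print.mediator_series <- function(x, ...) {
  cat(sprintf("Mediator regressions for '%s' at %d times; terms: %s\n",
              x$mediator, length(x$times), paste(x$terms, collapse = ", ")))
  invisible(x)
}
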