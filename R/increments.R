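#' Linear increment model: per-time regressions of increments on lagged values
#'
#' At every panel time \eqn{t_j} (with \eqn{j > \max(1, \mathrm{lag})}),
#' regresses the response's increment
#' \eqn{\Delta Y(t_j) = Y(t_j) - Y(t_{j-1})} across subjects on an intercept
#' plus each predictor's value at \eqn{t_{j-\mathrm{lag}}}, by ordinary least
#' squares over the subjects with complete cases at that time.  Increments are
#' always one-step differences of the response; `lag` applies to the
#' predictors and is counted in grid steps.  Subjects missing any needed value
#' at a time are dropped for that time only (complete-case per time, no
#' imputation).
#'
#' @param panel a [panel_data()] object.
#' @param response variable name whose increments are the outcome.
#' @param predictors variable names used (lagged) as regressors.
#' @param lag predictor lag in grid steps (>= 1).
#' @return Object of class `"increment_series"`: list with `times` (the times
#'   \eqn{t_j} at which a fit was produced), `coef` and `se` matrices (columns
#'   `(Intercept)` then predictors), complete-case counts `n`, and
#'   `skipped_times`.
#' @export
fit_increment_series <- function(panel, response, predictors, lag = 1) {
  stopifnot(inherits(panel, "panel_data"))
  if (lag < 1 || lag != round(lag)) stop("lag must be a positive integer", call. = FALSE)
  miss <- setdiff(c(response, predictors), panel$vars)
  if (length(miss)) stop("variable(s) not in panel: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  Tn <- length(panel$times)
  if (Tn <= lag) stop("panel has too few times for this lag", call. = FALSE)
  terms <- c("(Intercept)", predictors)
  p <- length(terms)
  jj <- seq.int(lag + 1L, Tn)
  K <- length(jj)
  coef <- matrix(NA_real_, K, p, dimnames = list(NULL, terms))
  se <- matrix(NA_real_, K, p, dimnames = list(NULL, terms))
  n <- integer(K)
  ok <- logical(K)
  V <- panel$values
  nsub <- length(panel$ids)
  for (k in seq_len(K)) {
    j <- jj[k]
    y <- V[, j, response] - V[, j - 1L, response]
    X <- cbind(rep(1, nsub),
               matrix(V[, j - lag, predictors], nsub, length(predictors)))
    colnames(X) <- terms
    cc <- stats::complete.cases(cbind(y, X))
    n[k] <- sum(cc)
    if (n[k] < p) next
    fit <- ols_solve(X[cc, , drop = FALSE], y[cc])
    if (is.null(fit)) next
    ok[k] <- TRUE
    coef[k, ] <- fit$coef
    res <- y[cc] - drop(X[cc, , drop = FALSE] %*% fit$coef)
    s2 <- if (n[k] > p) sum(res^2) / (n[k] - p) else NA_real_
    se[k, ] <- sqrt(s2 * diag(fit$XtX_inv))
  }
  if (!any(ok)) stop("no time point had enough complete cases to fit", call. = FALSE)
  structure(
    list(times = panel$times[jj[ok]],
         coef = coef[ok, , drop = FALSE],
         se = se[ok, , drop = FALSE],
         n = n[ok],
         skipped_times = panel$times[jj[!ok]],
         response = response, terms = terms, lag = lag),
    class = "increment_series"
  )
}

#' @export
print.increment_series <- function(x, ...) {
  cat(sprintf("Increment regressions: d%s on lag-%d %s at %d times\n",
              x$response, x$lag,
              paste(setdiff(x$terms, "(Intercept)"), collapse = ", "),
              length(x$times)))
  invisible(x)
}

#' @export
as.data.frame.increment_series <- function(x, ...) {
  K <- length(x$times)
  data.frame(time = rep(x$times, times = length(x$terms)),
             term = rep(x$terms, each = K),
             coefficient = as.vector(x$coef),
             se = as.vector(x$se),
             n = rep(x$n, times = length(x$terms)),
             stringsAsFactors = FALSE)
}

#' Cumulative coefficient curves for an increment series
#'
#' Running sums of the per-time coefficients, with variances accumulated
#' assuming independence across times -- the step-curve summary analogous to
#' cumulative regression functions in the additive hazard model.
#'
#' @param series an [fit_increment_series()] result.
#' @return Object of class `"cum_increments"`: list with `times`, `cumulative`
#'   and `var_cumulative` matrices.
#' @export
cumulative_coefficients <- function(series) {
  stopifnot(inherits(series, "increment_series"))
  if (!length(series$times)) stop("empty series", call. = FALSE)
  structure(list(times = series$times,
                 cumulative = col_cumsum(series$coef),
                 var_cumulative = col_cumsum(series$se^2),
                 terms = series$terms, response = series$response),
            class = "cum_increments")
}

#' @export
print.cum_increments <- function(x, ...) {
  K <- length(x$times)
  cat(sprintf("Cumulative increment coefficients for d%s at %d times; final values:\n",
              x$response, K))
  print(x$cumulative[K, ])
  invisible(x)
}

#' Direction-specific test of local dependence in a panel
#'
#' Tests whether the increments of `to_var` depend on the lagged values of
#' `from_var`, adjusting for lagged `adjust_for` variables (typically the
#' response's own past).  The per-time standardized coefficients
#' \eqn{z_t = \hat\beta_t / \mathrm{SE}_t} from [fit_increment_series()] are
#' aggregated into \eqn{Q = \sum_t z_t^2}.  Under `method = "chi2"`, \eqn{Q}
#' is referred to the chi-squared law with one degree of freedom per fitted
#' time; this reference is approximate because the per-time fits share
#' subjects.  Under `method = "permutation"`, whole `from_var` trajectories
#' are permuted across subjects (each subject's own history stays intact,
#' severing any cross-dependence) and \eqn{Q} is recomputed `n_perm` times.
#' Because the test is built on increments-on-lagged-values regressions it is
#' asymmetric: run it once per direction.
#'
#' @param panel a [panel_data()] object.
#' @param from_var candidate influencing variable.
#' @param to_var variable whose increments form the response.
#' @param adjust_for further variables entering (lagged) as adjustment.
#' @param lag predictor lag in grid steps.
#' @param method `"chi2"` or `"permutation"`.
#' @param n_perm number of permutations (>= 99) for the permutation method.
#' @param seed integer seed (permutation method).
#' @return Object of class `"lidep_test"`: list with `statistic`, `df`,
#'   `p_value`, per-time standardized contributions `z`, `times`, `method`,
#'   and `n_dropped` (times dropped for degenerate standard errors).
#' @export
test_local_dependence <- function(panel, from_var, to_var,
                                  adjust_for = character(), lag = 1,
                                  method = c("chi2", "permutation"),
                                  n_perm = 199, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "panel_data"))
  predictors <- unique(c(from_var, adjust_for))

  stat_of <- function(pn) {
    s <- fit_increment_series(pn, to_var, predictors, lag = lag)
    z <- s$coef[, from_var] / s$se[, from_var]
    keep <- is.finite(z) & s$se[, from_var] > 0
    list(z = z[keep], times = s$times[keep], dropped = sum(!keep))
  }
  obs <- stat_of(panel)
  statistic <- sum(obs$z^2)
  df <- length(obs$z)
  if (df == 0) stop("no usable time points for the test", call. = FALSE)

  if (method == "chi2") {
    p <- stats::pchisq(statistic, df = df, lower.tail = FALSE)
  } else {
    if (n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    n <- length(panel$ids)
    perm_stats <- vapply(seq_len(n_perm), function(r) {
      pp <- panel
      pp$values[, , from_var] <- panel$values[sample.int(n), , from_var]
      sum(stat_of(pp)$z^2)
    }, 0)
    p <- (1 + sum(perm_stats >= statistic)) / (n_perm + 1)
  }
  structure(list(from = from_var, to = to_var, statistic = statistic, df = df,
                 p_value = p, z = obs$z, times = obs$times, method = method,
                 n_dropped = obs$dropped, lag = lag),
            class = "lidep_test")
}

#' @export
print.lidep_test <- function(x, ...) {
  cat(sprintf("Local dependence test: %s -> d%s (lag %d, %s)\n",
              x$from, x$to, x$lag, x$method))
  cat(sprintf("Q = %.3f on %d time points, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
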