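#' Linear stochastic differential system
#'
#' Constructs a linear dynamic system \eqn{dX_t = A X_t\,dt + dB(t) + dW_t},
#' where `drift` is the matrix \eqn{A} whose entry \eqn{A_{ij}} is the rate at
#' which the current level of process \eqn{j} moves the drift of process
#' \eqn{i} (units 1/time), `input` is an optional deterministic forcing term
#' \eqn{dB(t)/dt} (level/time), and `noise_cov` is the diffusion covariance of
#' the white-noise term (level^2/time).  The influence structure of the system
#' is carried entirely by the off-diagonal pattern of `drift`: process \eqn{i}
#' is locally independent of process \eqn{j}, given the rest, exactly when
#' \eqn{A_{ij} = 0} (see [drift_to_graph()]).
#'
#' @param drift square numeric matrix \eqn{A} (p x p).
#' @param labels character vector of process names; defaults to the row names
#'   of `drift`, or `"1" ... "p"`.
#' @param input `NULL` (zero forcing, the default), a numeric p-vector for a
#'   constant forcing rate, or a function `t -> p-vector`.
#' @param noise_cov symmetric positive semi-definite p x p matrix, or `NULL`
#'   for a purely deterministic system.
#' @param psd_tol tolerance on the eigenvalues of `noise_cov` when checking
#'   positive semi-definiteness.
#' @return An object of class `"linear_sde"`.
#' @examples
#' A <- matrix(0, 3, 3, dimnames = list(1:3, 1:3))
#' A[2, 1] <- 1; A[3, 1] <- 1; A[3, 2] <- 1   # 1 -> 2 -> 3 and 1 -> 3
#' m <- linear_sde(A)
#' expected_state(m, c(1, 0, 0), t = 2)
#' @seealso [expected_state()], [simulate.linear_sde()], [path_effects()]
#' @export
linear_sde <- function(drift, labels = NULL, input = NULL, noise_cov = NULL,
                       psd_tol = 1e-10) {
  drift <- as.matrix(drift)
  if (nrow(drift) != ncol(drift)) stop("drift must be a square matrix", call. = FALSE)
  p <- nrow(drift)
  if (is.null(labels)) labels <- rownames(drift) %||% as.character(seq_len(p))
  labels <- as.character(labels)
  if (length(labels) != p) stop("length(labels) must equal nrow(drift)", call. = FALSE)
  if (anyDuplicated(labels)) stop("labels must be unique", call. = FALSE)
  dimnames(drift) <- list(labels, labels)

  if (is.numeric(input)) {
    if (length(input) != p) stop("constant input must have length p", call. = FALSE)
    const <- input
    input <- function(t) const
    attr(input, "constant") <- const
  } else if (!is.null(input) && !is.function(input)) {
    stop("input must be NULL, a numeric vector, or a function of t", call. = FALSE)
  }

  if (is.null(noise_cov)) {
    noise_cov <- matrix(0, p, p)
  } else {
    noise_cov <- as.matrix(noise_cov)
    if (!all(dim(noise_cov) == p)) stop("noise_cov must be p x p", call. = FALSE)
    if (max(abs(noise_cov - t(noise_cov))) > psd_tol * max(1, max(abs(noise_cov)))) {
      stop("noise_cov must be symmetric", call. = FALSE)
    }
    noise_cov <- (noise_cov + t(noise_cov)) / 2
    psd_sqrt(noise_cov, tol = psd_tol)  # validates PSD
  }
  dimnames(noise_cov) <- list(labels, labels)

  structure(
    list(labels = labels, drift = drift, input = input, noise_cov = noise_cov,
         psd_tol = psd_tol),
    class = "linear_sde"
  )
}

#' @export
print.linear_sde <- function(x, ...) {
  cat(sprintf("Linear SDE system with %d processes: %s\n",
              length(x$labels), paste(x$labels, collapse = ", ")))
  cat("Drift matrix A:\n"); print(x$drift)
  if (!is.null(x$input)) cat("Deterministic input: present\n")
  if (any(x$noise_cov != 0)) { cat("Noise covariance:\n"); print(x$noise_cov) }
  invisible(x)
}

stop_if_input <- function(model, what) {
  if (!is.null(model$input)) {
    stop(sprintf(paste0("%s assumes a zero deterministic input (the closed-form ",
                        "conditional expectation E(X_t | X_0) = exp(At) X_0 holds ",
                        "only then); this model has a non-zero input term"), what),
         call. = FALSE)
  }
}

#' Expected state of a linear system
#'
#' Conditional expectation \eqn{E(X_t \mid X_0 = x_0) = \exp(A t)\, x_0} for a
#' linear system with zero deterministic input.  Exact (up to the matrix
#' exponential routine) for any drift matrix, cyclic or not.
#'
#' @param model a [linear_sde()] object with zero input.
#' @param x0 numeric p-vector of initial levels.
#' @param t nonnegative time horizon.
#' @return Named numeric p-vector.
#' @export
expected_state <- function(model, x0, t) {
  stopifnot(inherits(model, "linear_sde"))
  stop_if_input(model, "expected_state()")
  p <- length(model$labels)
  if (length(x0) != p) stop("x0 must have length p", call. = FALSE)
  if (t < 0) stop("t must be nonnegative", call. = FALSE)
  out <- drop(matexp(model$drift * t) %*% x0)
  names(out) <- model$labels
  out
}

#' Simulate trajectories of a linear stochastic differential system
#'
#' Euler--Maruyama simulation on a user-supplied time grid.  The step size is
#' the grid spacing, so the grid controls accuracy; with `noise_cov = 0` a
#' single path solves the ODE up to the scheme's discretization error.
#' Identical seeds give identical ensembles.
#'
#' @param object a [linear_sde()] model.
#' @param nsim number of independent paths.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param x0 initial p-vector (recycled across paths).
#' @param times strictly increasing time grid starting at 0.
#' @param ... unused.
#' @return An object of class `"sde_paths"`: list with `times`, a
#'   `nsim x length(times) x p` array `states`, and the `seed` used.
#' @importFrom stats simulate rnorm
#' @export
simulate.linear_sde <- function(object, nsim = 1, seed = NULL, x0, times, ...) {
  if (nsim < 1) stop("nsim must be >= 1", call. = FALSE)
  times <- as.numeric(times)
  if (length(times) < 1 || times[1] != 0 || is.unsorted(times, strictly = TRUE)) {
    stop("times must be a strictly increasing grid starting at 0", call. = FALSE)
  }
  p <- length(object$labels)
  if (length(x0) != p) stop("x0 must have length p", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  L <- psd_sqrt(object$noise_cov, tol = object$psd_tol)
  noisy <- any(object$noise_cov != 0)
  K <- length(times)
  states <- array(NA_real_, dim = c(nsim, K, p),
                  dimnames = list(NULL, NULL, object$labels))
  states[, 1, ] <- matrix(x0, nsim, p, byrow = TRUE)
  At <- t(object$drift)
  cur <- states[, 1, , drop = TRUE]
  if (nsim == 1) cur <- matrix(cur, 1, p)
  for (k in seq_len(K - 1)) {
    dt <- times[k + 1] - times[k]
    inc <- cur %*% At * dt
    if (!is.null(object$input)) {
      inc <- inc + matrix(object$input(times[k]), nsim, p, byrow = TRUE) * dt
    }
    if (noisy) {
      inc <- inc + matrix(rnorm(nsim * p), nsim, p) %*% t(L) * sqrt(dt)
    }
    cur <- cur + inc
    states[, k + 1, ] <- cur
  }
  structure(list(times = times, states = states, labels = object$labels,
                 seed = seed),
            class = "sde_paths")
}

#' @export
print.sde_paths <- function(x, ...) {
  cat(sprintf("SDE trajectory ensemble: %d path(s), %d grid points, processes %s\n",
              dim(x$states)[1], dim(x$states)[2], paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Long-format view of a trajectory ensemble
#'
#' @param x an object returned by [simulate.linear_sde()].
#' @param ... unused.
#' @return `data.frame` with columns `path_id`, `time`, one column per process.
#' @export
as.data.frame.sde_paths <- function(x, ...) {
  n <- dim(x$states)[1]; K <- dim(x$states)[2]
  out <- data.frame(path_id = rep(seq_len(n), each = K),
                    time = rep(x$times, times = n))
  for (j in seq_along(x$labels)) {
    out[[x$labels[j]]] <- as.vector(t(matrix(x$states[, , j], n, K)))
  }
  out
}
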