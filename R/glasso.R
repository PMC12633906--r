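#' Elementwise penalty matrix
#'
#' Container for the symmetric nonnegative penalty matrix `lambda_ij` of the
#' penalized log-determinant problem. A scalar is expanded to a uniform
#' penalty (the classical graphical lasso).
#'
#' @param values `p x p` symmetric matrix of nonnegative penalties, or a
#'   single nonnegative scalar together with `p`.
#' @param p Dimension, required when `values` is scalar.
#' @param alpha Optional scalar recorded when the matrix was built by
#'   [adaptive_penalties()].
#' @param epsilons Optional vector of stabilising constants recorded by
#'   [adaptive_penalties()].
#' @return An object of class `penalty_matrix` (a matrix with attributes).
#' @export
penalty_matrix <- function(values, p = NULL, alpha = NULL, epsilons = NULL) {
  if (length(values) == 1L) {
    if (is.null(p)) .stop_arg("`p` is required for a scalar penalty")
    values <- matrix(values, p, p)
  }
  values <- as.matrix(values)
  if (!isSymmetric(unname(values), tol = 1e-10))
    .stop_arg("penalty matrix must be symmetric")
  if (any(!is.finite(values)) || any(values < 0))
    .stop_arg("penalties must be finite and nonnegative")
  structure(values, alpha = alpha, epsilons = epsilons,
            class = c("penalty_matrix", "matrix"))
}

.as_penalty <- function(penalty, p) {
  if (inherits(penalty, "penalty_matrix")) {
    if (nrow(penalty) != p) .stop_arg("penalty dimension does not match S")
    return(penalty)
  }
  penalty_matrix(penalty, p = if (length(penalty) == 1L) p else NULL)
}

#' Graphical lasso with an elementwise penalty matrix
#'
#' Solves `argmin_{Theta > 0} tr(Theta S) - log det(Theta) +
#' sum_ij lambda_ij |theta_ij|` by block coordinate descent over columns of
#' `W = Theta^{-1}`, with a per-column lasso subproblem that supports a
#' different penalty per entry. The diagonal is penalized, so
#' `W_ii = S_ii + lambda_ii` at the solution.
#'
#' @param S `p x p` symmetric positive semidefinite matrix (rank deficiency
#'   is permitted; the penalty regularizes the problem). The diagonal must
#'   be strictly positive.
#' @param penalty A [penalty_matrix()], a symmetric matrix, or a single
#'   nonnegative scalar (uniform penalty).
#' @param tol Convergence tolerance: the mean absolute change of the
#'   off-diagonal entries of `W` between sweeps must fall below
#'   `tol * mean(|S_offdiag|)`. Default `1e-4`.
#' @param max_iter Maximum outer sweeps; if reached, the estimate is
#'   returned with `converged = FALSE` and a warning. Default 200.
#' @param warm Optional `precision_estimate` used to warm-start the solver
#'   (pure efficiency; does not change the solution).
#' @param zero_tol Entries with `|theta_ij| < zero_tol` are treated as exact
#'   zeros when forming edge sets. Default `1e-8`.
#' @return An object of class `precision_estimate`: `theta` (symmetric
#'   positive definite), `covariance_hat` (`W`), `objective_value`,
#'   `objective_trace` (per sweep), `converged`, `iterations`,
#'   `kkt_residual`, and the `penalty` used.
#' @export
solve_glasso <- function(S, penalty, tol = 1e-4, max_iter = 200L,
                         warm = NULL, zero_tol = .EDGE_ZERO_TOL) {
  S <- as.matrix(S)
  if (!isSymmetric(unname(S), tol = 1e-8))
    .stop_arg("`S` must be symmetric")
  if (any(diag(S) <= 0))
    .stop_arg("`S` must have a strictly positive diagonal")
  if (!is.numeric(tol) || tol <= 0) .stop_arg("`tol` must be positive")
  p <- nrow(S)
  Rho <- .as_penalty(penalty, p)
  S <- (S + t(S)) / 2

  W0 <- B0 <- NULL
  if (!is.null(warm) && inherits(warm, "precision_estimate") &&
      nrow(warm$theta) == p) {
    W0 <- warm$covariance_hat
    B0 <- attr(warm, "B")
  }
  fit <- .glasso_core(S, unclass(Rho), tol, as.integer(max_iter), W0, B0)
  if (!fit$converged)
    warning(sprintf("glasso did not reach tol %g within %d sweeps",
                    tol, max_iter), call. = FALSE)

  theta <- (fit$theta + t(fit$theta)) / 2
  W <- (fit$w + t(fit$w)) / 2
  res <- kkt_residual(S, theta, W = W, penalty = Rho, zero_tol = zero_tol)
  structure(list(theta = theta,
                 covariance_hat = W,
                 objective_value = fit$objective,
                 objective_trace = fit$objective_trace,
                 converged = fit$converged,
                 iterations = fit$iterations,
                 kkt_residual = res,
                 penalty = Rho),
            B = fit$B,
            class = "precision_estimate")
}

#' @export
print.precision_estimate <- function(x, ...) {
  p <- nrow(x$theta)
  cat(sprintf(
    "Precision estimate: p = %d, %d edges, objective %.6g\n",
    p, nrow(precision_edges(x)), x$objective_value))
  cat(sprintf("  converged: %s in %d sweeps (KKT residual %.3g)\n",
              x$converged, x$iterations, x$kkt_residual))
  invisible(x)
}

#' Edge set of a precision estimate
#'
#' @param theta A `precision_estimate` or a precision matrix.
#' @param zero_tol Zero threshold on `|theta_ij|`.
#' @return Two-column integer matrix of node pairs `i < j`.
#' @export
precision_edges <- function(theta, zero_tol = .EDGE_ZERO_TOL) {
  if (inherits(theta, "precision_estimate")) theta <- theta$theta
  up <- which(abs(theta) >= zero_tol & upper.tri(theta), arr.ind = TRUE)
  up <- up[order(up[, 1L], up[, 2L]), , drop = FALSE]
  dimnames(up) <- list(NULL, c("i", "j"))
  up
}

#' Stationarity (KKT) residual of a candidate solution
#'
#' Maximum violation of the subgradient optimality conditions of the
#' penalized log-determinant objective: off the diagonal,
#' `|S_ij - W_ij| <= lambda_ij` where `theta_ij = 0` and
#' `S_ij - W_ij + lambda_ij sign(theta_ij) = 0` where `theta_ij != 0`;
#' on the diagonal, `W_ii = S_ii + lambda_ii`.
#'
#' @param S Input covariance matrix.
#' @param theta Candidate precision matrix (positive definite) or a
#'   `precision_estimate`.
#' @param W Its inverse; computed with [solve()] when missing.
#' @param penalty Penalty matrix or scalar.
#' @param zero_tol Zero threshold on `|theta_ij|`.
#' @return Nonnegative scalar, the maximum elementwise violation.
#' @export
kkt_residual <- function(S, theta, W = NULL, penalty,
                         zero_tol = .EDGE_ZERO_TOL) {
  if (inherits(theta, "precision_estimate")) {
    if (is.null(W)) W <- theta$covariance_hat
    theta <- theta$theta
  }
  S <- as.matrix(S)
  p <- nrow(S)
  Rho <- .as_penalty(penalty, p)
  if (is.null(W)) {
    W <- tryCatch(solve(theta),
                  error = function(e) .stop_arg("`theta` is singular"))
  }
  G <- S - W                       # gradient of the smooth part is S - W
  off <- upper.tri(S) | lower.tri(S)
  viol_zero <- pmax(0, abs(G) - Rho)         # inactive entries
  viol_sign <- abs(G + Rho * sign(theta))    # active entries
  active <- abs(theta) >= zero_tol
  v_off <- ifelse(active, viol_sign, viol_zero)[off]
  v_diag <- abs(diag(W) - diag(S) - diag(unclass(Rho)))
  max(v_off, v_diag, 0)
}
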