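#' Adaptive scale-free penalties from a current precision iterate
#'
#' Builds the elementwise penalty matrix that approximates a power-law
#' degree prior: with `r_i = sum_{j != i} |theta_ij|` (row L1 norm excluding
#' the diagonal) and `eps_i = theta_ii`,
#' `lambda_ij = alpha * (1/(r_i + eps_i) + 1/(r_j + eps_j))` off the
#' diagonal and `lambda_ii = 2 * alpha / eps_i`. Rows that already carry
#' many strong edges (hubs) receive smaller penalties, so further edges on
#' hubs are cheap — the reweighting encourages hub formation.
#'
#' @param theta Current precision iterate, positive definite with a strictly
#'   positive diagonal (or a `precision_estimate`).
#' @param alpha Positive scale of the penalty.
#' @return A [penalty_matrix()] with `alpha` and `epsilons` recorded.
#' @export
adaptive_penalties <- function(theta, alpha) {
  if (inherits(theta, "precision_estimate")) theta <- theta$theta
  theta <- as.matrix(theta)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    .stop_arg("`alpha` must be a positive scalar")
  eps <- diag(theta)
  if (any(eps <= 0))
    .stop_arg("`theta` must have a strictly positive diagonal")
  r <- rowSums(abs(theta)) - abs(eps)
  inv <- 1 / (r + eps)
  lam <- alpha * outer(inv, inv, `+`)
  diag(lam) <- 2 * alpha / eps
  penalty_matrix(lam, alpha = alpha, epsilons = eps)
}

#' Scale-free graphical lasso (reweighted glasso)
#'
#' Starting from the identity, runs `m` glasso solves; before each solve the
#' penalty matrix is rebuilt from the previous iterate with
#' [adaptive_penalties()]. With `m = 1` this is a plain glasso at the
#' identity-induced uniform penalty `2 * alpha`; `m = 2` (one reweighting
#' step, the default) is typically sufficient.
#'
#' @param S Symmetric PSD input covariance.
#' @param alpha Positive penalty scale.
#' @param m Number of glasso solves (>= 1). Default 2.
#' @param tol,max_iter,zero_tol Passed to [solve_glasso()].
#' @param warm Optional `precision_estimate` to warm-start the first solve.
#' @return A `precision_estimate` from the final step; its `penalty` field
#'   holds the last adaptive penalty used.
#' @export
sfglasso <- function(S, alpha, m = 2L, tol = 1e-4, max_iter = 200L,
                     zero_tol = .EDGE_ZERO_TOL, warm = NULL) {
  if (!is.numeric(m) || length(m) != 1L || m < 1)
    .stop_arg("`m` must be an integer >= 1")
  p <- nrow(S)
  theta_cur <- diag(p)
  fit <- warm
  for (step in seq_len(m)) {
    pen <- adaptive_penalties(theta_cur, alpha)
    fit <- solve_glasso(S, pen, tol = tol, max_iter = max_iter,
                        warm = fit, zero_tol = zero_tol)
    theta_cur <- fit$theta
  }
  fit
}
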