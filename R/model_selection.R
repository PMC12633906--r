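#' Extended BIC for a Gaussian graphical model at one time point
#'
#' `eBIC_gamma = -n * l(Theta, S) + log(n) * df + 4 * gamma * log(p) * df`
#' with the (scaled) log-likelihood `l = log det(Theta) - tr(S Theta)` and
#' `df` the edge count (nonzero off-diagonal upper-triangle entries).
#' Natural logarithms throughout. `gamma = 0` reduces to the BIC; larger
#' `gamma` yields sparser selected models.
#'
#' @param theta Precision matrix (positive definite) or
#'   `precision_estimate`.
#' @param S Covariance matrix the model was fitted to.
#' @param n_eff Effective sample size behind `S` (>= 1). For smoothed
#'   covariances this is the total number of observations at time points
#'   with nonzero kernel weight ([smoothed_covariance()] field `n_eff`).
#' @param gamma Nonnegative eBIC parameter. Default 0.5.
#' @param zero_tol Zero threshold for `df`.
#' @return The eBIC score (smaller is better).
#' @export
ebic <- function(theta, S, n_eff, gamma = 0.5, zero_tol = .EDGE_ZERO_TOL) {
  if (inherits(theta, "precision_estimate")) theta <- theta$theta
  if (n_eff < 1) .stop_arg("`n_eff` must be >= 1")
  if (gamma < 0) .stop_arg("`gamma` must be nonnegative")
  p <- nrow(theta)
  ch <- tryCatch(chol(theta),
                 error = function(e)
                   .stop_arg("`theta` must be positive definite"))
  loglik <- 2 * sum(log(diag(ch))) - sum(S * theta)
  df <- nrow(precision_edges(theta, zero_tol))
  -n_eff * loglik + log(n_eff) * df + 4 * gamma * log(p) * df
}

#' eBIC model selection over a candidate set
#'
#' Scores each fitted candidate with [ebic()] and returns the minimizer.
#' Ties are broken toward the sparsest candidate (smaller `df`), then toward
#' the larger tuning-parameter value.
#'
#' @param candidates List of `precision_estimate` objects fitted to `S`.
#' @param S Covariance matrix.
#' @param n_eff Effective sample size (see [ebic()]).
#' @param gamma eBIC parameter.
#' @param values Optional numeric vector of the tuning-parameter grid, used
#'   for reporting and the final tie-break.
#' @param zero_tol Zero threshold for `df`.
#' @return An object of class `model_selection`: `candidate_values`,
#'   `ebic_scores`, `selected_index`, `gamma`, `df_per_candidate`,
#'   `effective_n`.
#' @export
select_model <- function(candidates, S, n_eff, gamma = 0.5, values = NULL,
                         zero_tol = .EDGE_ZERO_TOL) {
  if (length(candidates) == 0L) .stop_arg("`candidates` must be nonempty")
  scores <- vapply(candidates, ebic, 0, S = S, n_eff = n_eff,
                   gamma = gamma, zero_tol = zero_tol)
  dfs <- vapply(candidates, function(fit)
    nrow(precision_edges(fit, zero_tol)), 0L)
  if (is.null(values)) values <- seq_along(candidates)
  best <- which(scores == min(scores))
  if (length(best) > 1L) best <- best[dfs[best] == min(dfs[best])]
  if (length(best) > 1L) best <- best[which.max(values[best])]
  structure(list(candidate_values = values,
                 ebic_scores = scores,
                 selected_index = best[1L],
                 gamma = gamma,
                 df_per_candidate = dfs,
                 effective_n = n_eff),
            class = "model_selection")
}

#' Logarithmically spaced tuning-parameter grid
#'
#' @param lo,hi Positive endpoints, `lo < hi`; both are included.
#' @param n Number of values (>= 2). Default 25 over `[0.05, 0.3]`, the
#'   grid used for the simulation benchmarks.
#' @return Numeric vector of `n` log-uniformly spaced values.
#' @export
log_grid <- function(lo = 0.05, hi = 0.3, n = 25L) {
  if (!(lo > 0 && hi > lo)) .stop_arg("need 0 < lo < hi")
  if (n < 2L) .stop_arg("`n` must be >= 2")
  g <- exp(seq(log(lo), log(hi), length.out = n))
  g[1L] <- lo
  g[n] <- hi
  g
}
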