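# The five estimators over time. All share one per-time-point engine:
# fit every candidate on the grid (warm-started along the grid), score with
# eBIC at the effective sample size behind the covariance, keep the argmin.

.fit_grid <- function(S, n_eff, method, grid, gamma, m, tol, max_iter,
                      zero_tol, verbose = FALSE, label = "") {
  fits <- vector("list", length(grid))
  warm <- NULL
  for (g in seq_along(grid)) {
    fits[[g]] <- if (method == "sfglasso") {
      sfglasso(S, alpha = grid[g], m = m, tol = tol, max_iter = max_iter,
               zero_tol = zero_tol, warm = warm)
    } else {
      solve_glasso(S, penalty_matrix(grid[g], p = nrow(S)), tol = tol,
                   max_iter = max_iter, warm = warm, zero_tol = zero_tol)
    }
    warm <- fits[[g]]
  }
  sel <- select_model(fits, S, n_eff, gamma = gamma, values = grid,
                      zero_tol = zero_tol)
  best <- fits[[sel$selected_index]]
  if (verbose)
    message(sprintf(
      "%s: value %.4g, df %d, eBIC %.6g, %d sweeps%s", label,
      grid[sel$selected_index], sel$df_per_candidate[sel$selected_index],
      sel$ebic_scores[sel$selected_index], best$iterations,
      if (best$converged) "" else " [not converged]"))
  list(fit = best, selection = sel)
}

.tv_network <- function(data, spec, method, grid, gamma, m, tol, max_iter,
                        zero_tol, fallback, verbose, extra_params) {
  thetas <- vector("list", data$N)
  edges <- vector("list", data$N)
  selection <- vector("list", data$N)
  for (k in seq_len(data$N)) {
    res <- tryCatch({
      sc <- smoothed_covariance(data, data$time_points[k], spec,
                                fallback = fallback)
      .fit_grid(sc$matrix, sc$n_eff, method, grid, gamma, m, tol,
                max_iter, zero_tol, verbose,
                label = sprintf("t[%d] = %.3f", k, data$time_points[k]))
    }, error = function(e)
      .stop_arg(sprintf("fit failed at time point %d (t = %g): %s",
                        k, data$time_points[k], conditionMessage(e))))
    thetas[[k]] <- res$fit$theta
    edges[[k]] <- precision_edges(res$fit, zero_tol)
    selection[[k]] <- res$selection
  }
  dynamic_network(data$gene_ids, data$time_points, edges, thetas = thetas,
                  time_labels = data$time_labels, selection = selection,
                  params = c(list(h = spec$bandwidth, kernel = spec$kernel,
                                  gamma = gamma, grid = grid),
                             extra_params))
}

#' Time-varying scale-free graphical lasso
#'
#' At each time point, forms the kernel-smoothed covariance and fits the
#' reweighted scale-free glasso ([sfglasso()], identity initialization, `m`
#' solves) for every `alpha` on the grid; the model at each time point is
#' chosen by [ebic()]. Cost is linear in the number of time points.
#'
#' @param data An [expression_ts()] object.
#' @param h Kernel bandwidth on the rescaled `[0, 1]` time axis. Default 1.
#' @param kernel Kernel name, see [kernel_spec()].
#' @param alpha_grid Candidate `alpha` values; default 25 log-spaced values
#'   in `[0.05, 0.3]`.
#' @param gamma eBIC parameter. Default 0.5.
#' @param m Reweighting solves per fit. Default 2.
#' @param tol,max_iter,zero_tol Solver controls, see [solve_glasso()].
#' @param fallback Nearest-neighbour fallback for tiny bandwidths, see
#'   [compute_weights()].
#' @param verbose Log the selected value, df and eBIC per time point.
#' @return A [dynamic_network()] with per-time precision matrices and
#'   `model_selection` records.
#' @export
tvsfglasso <- function(data, h = 1, kernel = "epanechnikov",
                       alpha_grid = log_grid(0.05, 0.3, 25L), gamma = 0.5,
                       m = 2L, tol = 1e-4, max_iter = 200L,
                       zero_tol = .EDGE_ZERO_TOL, fallback = FALSE,
                       verbose = FALSE) {
  spec <- kernel_spec(kernel, h)
  .tv_network(data, spec, "sfglasso", alpha_grid, gamma, m, tol, max_iter,
              zero_tol, fallback, verbose,
              list(method = "tvsfglasso", m = m))
}

#' Time-varying graphical lasso (uniform penalty)
#'
#' As [tvsfglasso()] but with a uniform penalty `lambda` per candidate and
#' no reweighting.
#'
#' @inheritParams tvsfglasso
#' @param lambda_grid Candidate uniform penalties.
#' @return A [dynamic_network()].
#' @export
tvglasso <- function(data, h = 1, kernel = "epanechnikov",
                     lambda_grid = log_grid(0.05, 0.3, 25L), gamma = 0.5,
                     tol = 1e-4, max_iter = 200L,
                     zero_tol = .EDGE_ZERO_TOL, fallback = FALSE,
                     verbose = FALSE) {
  spec <- kernel_spec(kernel, h)
  .tv_network(data, spec, "glasso", lambda_grid, gamma, m = 1L, tol,
              max_iter, zero_tol, fallback, verbose,
              list(method = "tvglasso"))
}

#' Pointwise (unsmoothed) estimators
#'
#' Fits a glasso or scale-free glasso independently at each time point,
#' using the per-time-point sample covariance only (no kernel smoothing; the
#' effective sample size is `n_k`).
#'
#' @inheritParams tvsfglasso
#' @param method `"glasso"` or `"sfglasso"`.
#' @param grid Tuning-parameter grid (`lambda` or `alpha`).
#' @return A [dynamic_network()].
#' @export
pointwise_estimators <- function(data, method = c("glasso", "sfglasso"),
                                 grid = log_grid(0.05, 0.3, 25L),
                                 gamma = 0.5, m = 2L, tol = 1e-4,
                                 max_iter = 200L,
                                 zero_tol = .EDGE_ZERO_TOL,
                                 verbose = FALSE) {
  method <- match.arg(method)
  thetas <- vector("list", data$N)
  edges <- vector("list", data$N)
  selection <- vector("list", data$N)
  for (k in seq_len(data$N)) {
    S_k <- per_time_covariance(data$blocks[[k]])
    res <- .fit_grid(S_k, data$n_k[k], method, grid, gamma, m, tol,
                     max_iter, zero_tol, verbose,
                     label = sprintf("t[%d]", k))
    thetas[[k]] <- res$fit$theta
    edges[[k]] <- precision_edges(res$fit, zero_tol)
    selection[[k]] <- res$selection
  }
  dynamic_network(data$gene_ids, data$time_points, edges, thetas = thetas,
                  time_labels = data$time_labels, selection = selection,
                  params = list(method = paste0("pointwise_", method),
                                gamma = gamma, grid = grid, m = m))
}

#' Pooled graphical lasso
#'
#' Estimates one covariance matrix from the whole time series (all
#' `sum(n_k)` observations pooled) and fits a single glasso, selected by
#' eBIC. A baseline for time series whose network is (nearly) static.
#'
#' @inheritParams tvglasso
#' @return A list of class `pooled_fit`: `edges`, `estimate`
#'   (`precision_estimate`), `selection`, `node_ids`.
#' @export
pooled_glasso <- function(data, lambda_grid = log_grid(0.05, 0.3, 25L),
                          gamma = 0.5, tol = 1e-4, max_iter = 200L,
                          zero_tol = .EDGE_ZERO_TOL, verbose = FALSE) {
  X <- .stack_obs(data)
  S <- crossprod(X) / nrow(X)
  res <- .fit_grid(S, nrow(X), "glasso", lambda_grid, gamma, 1L, tol,
                   max_iter, zero_tol, verbose, label = "pooled")
  structure(list(edges = precision_edges(res$fit, zero_tol),
                 estimate = res$fit,
                 selection = res$selection,
                 node_ids = data$gene_ids),
            class = "pooled_fit")
}

#' @export
print.pooled_fit <- function(x, ...) {
  cat(sprintf("Pooled glasso fit: %d nodes, %d edges (lambda = %.4g)\n",
              length(x$node_ids), nrow(x$edges),
              x$selection$candidate_values[x$selection$selected_index]))
  invisible(x)
}
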