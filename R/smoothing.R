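#' Kernel specification for covariance smoothing
#'
#' The smoothing weights are `w_tj(t) = K(|t_j - t| / h)`. The default kernel
#' is the standard Epanechnikov `K(a) = 0.75 (1 - a^2)` on `|a| <= 1`. An
#' alternative variant `K(a) = 0.75 (1 - a)^2` (`"epanechnikov_printed"`) is
#' provided for reproducibility of analyses that used that form.
#'
#' @param kernel Kernel name, `"epanechnikov"` (default) or
#'   `"epanechnikov_printed"`.
#' @param bandwidth Positive bandwidth `h`, on the rescaled `[0, 1]` time
#'   axis. Default 1.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(kernel = c("epanechnikov", "epanechnikov_printed"),
                        bandwidth = 1) {
  kernel <- match.arg(kernel)
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L ||
      !is.finite(bandwidth) || bandwidth <= 0)
    .stop_arg("`bandwidth` must be a positive number")
  structure(list(kernel = kernel, bandwidth = bandwidth),
            class = "kernel_spec")
}

#' Evaluate the smoothing kernel
#'
#' @param a Nonnegative scaled distance(s) `|t_j - t| / h`.
#' @param spec A [kernel_spec()].
#' @return Kernel value(s), zero outside `[0, 1]`.
#' @export
kernel_weight <- function(a, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (any(!is.finite(a)) || any(a < 0))
    .stop_arg("kernel argument `a` must be nonnegative and finite")
  inside <- a <= 1
  out <- numeric(length(a))
  if (spec$kernel == "epanechnikov") {
    out[inside] <- 0.75 * (1 - a[inside]^2)
  } else {
    out[inside] <- 0.75 * (1 - a[inside])^2
  }
  out
}

#' Kernel weights of all time points relative to a query time
#'
#' @param time_points Rescaled time points `t_j` in `[0, 1]`.
#' @param t Query time in `[0, 1]`.
#' @param spec A [kernel_spec()].
#' @param fallback If `TRUE` and no time point falls inside the kernel
#'   support, put weight 1 on the nearest time point instead of failing.
#' @return Nonnegative weight vector of length `length(time_points)`.
#' @export
compute_weights <- function(time_points, t, spec, fallback = FALSE) {
  if (length(time_points) == 0L) .stop_arg("`time_points` must be nonempty")
  if (t < 0 || t > 1) .stop_arg("query time `t` must lie in [0, 1]")
  w <- kernel_weight(abs(time_points - t) / spec$bandwidth, spec)
  if (all(w == 0)) {
    if (fallback) {
      w[which.min(abs(time_points - t))] <- 1
    } else {
      .stop_arg(sprintf(
        "no time point within kernel support at t = %g (h = %g); %s",
        t, spec$bandwidth,
        "increase the bandwidth or enable the nearest-neighbour fallback"))
    }
  }
  w
}

#' Per-time-point sample covariance over replicates
#'
#' `S_k = (1/n_k) sum_j x_j x_j'` (divisor `n_k`, not `n_k - 1`; the data
#' are assumed centred).
#'
#' @param block `n_k x p` matrix of replicate observations at one time point.
#' @return `p x p` symmetric positive semidefinite matrix.
#' @export
per_time_covariance <- function(block) {
  block <- as.matrix(block)
  if (nrow(block) < 1L) .stop_arg("replicate block is empty")
  crossprod(block) / nrow(block)
}

#' Kernel-smoothed covariance at a query time
#'
#' With a single observation per time point this is the weighted average of
#' the per-observation outer products; with replicates it is the weighted
#' average of the per-time-point sample covariances `S_k`, using the same
#' kernel weights. The two coincide when every `n_k = 1`.
#'
#' @param data An [expression_ts()] object.
#' @param t Query time in `[0, 1]` (rescaled axis).
#' @param spec A [kernel_spec()].
#' @param fallback Passed to [compute_weights()].
#' @return An object of class `smoothed_cov`: fields `matrix` (p x p),
#'   `query_time`, `weights`, `mode` (`"pooled_samples"` or
#'   `"replicate_blocks"`), and `n_eff` (total observations at supported
#'   time points, used as the sample size in [ebic()]).
#' @export
smoothed_covariance <- function(data, t, spec, fallback = FALSE) {
  stopifnot(inherits(data, "expr_ts"))
  w <- compute_weights(data$time_points, t, spec, fallback = fallback)
  wn <- w / sum(w)   # normalize first so a single-support weight is exactly 1
  S <- matrix(0, data$p, data$p)
  for (k in which(wn > 0))
    S <- S + wn[k] * per_time_covariance(data$blocks[[k]])
  S <- (S + t(S)) / 2
  structure(list(matrix = S,
                 query_time = t,
                 weights = w,
                 mode = if (all(data$n_k == 1L)) "pooled_samples"
                        else "replicate_blocks",
                 n_eff = sum(data$n_k[w > 0])),
            class = "smoothed_cov")
}
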