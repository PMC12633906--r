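test_that("kernel_weight matches both kernel variants and rejects bad input", {
  std <- kernel_spec("epanechnikov", 1)
  prt <- kernel_spec("epanechnikov_printed", 1)
  expect_equal(kernel_weight(0, std), 0.75)
  expect_equal(kernel_weight(c(1, 2), std), c(0, 0))
  expect_equal(kernel_weight(0.5, std), 0.5625)
  expect_equal(kernel_weight(0.5, prt), 0.1875)
  expect_equal(kernel_weight(0, prt), 0.75)
  expect_error(kernel_weight(-0.1, std), "nonnegative")
  expect_error(kernel_spec(bandwidth = 0), "positive")
})

test_that("compute_weights evaluates the kernel at scaled distances", {
  spec <- kernel_spec(bandwidth = 1)
  expect_equal(compute_weights(c(0, 0.5, 1), 0.5, spec),
               c(0.5625, 0.75, 0.5625))
  # huge bandwidth: all weights ~ K(0)
  w <- compute_weights(seq(0, 1, 0.25), 0.4, kernel_spec(bandwidth = 1e7))
  expect_true(max(abs(w - 0.75)) < 1e-10)
  expect_equal(compute_weights(c(0, 0.5, 1), 0.5,
                               kernel_spec(bandwidth = 0.1)),
               c(0, 0.75, 0))
})

test_that("empty kernel support errors by default, falls back when asked", {
  spec <- kernel_spec(bandwidth = 0.05)
  expect_error(compute_weights(c(0, 1), 0.5, spec), "t = 0.5")
  w <- compute_weights(c(0, 1), 0.4, spec, fallback = TRUE)
  expect_equal(w, c(1, 0))
})

test_that("per_time_covariance uses divisor n_k and matches outer products", {
  expect_equal(per_time_covariance(matrix(c(1, 2), 1)),
               matrix(c(1, 2, 2, 4), 2))
  expect_equal(per_time_covariance(rbind(c(1, 0), c(-1, 0))),
               matrix(c(1, 0, 0, 0), 2))
  expect_error(per_time_covariance(matrix(0, 0, 2)), "empty")
  # Monte-Carlo: covariance of standard Gaussians is the identity
  set.seed(7)
  S <- per_time_covariance(matrix(rnorm(3e5), 1e5, 3))
  expect_lt(max(abs(S - diag(3))), 0.02)
})

test_that("smoothed_covariance averages per-time covariances with kernel weights", {
  # three blocks with exact per-time covariances I, 2I, 4I
  blocks <- lapply(c(1, 2, 4), diag_cov_block)
  data <- expression_ts(blocks, times = c(0, 0.5, 1), center = FALSE)
  sc <- smoothed_covariance(data, 0.5, kernel_spec(bandwidth = 1))
  expect_equal(sc$weights, c(0.5625, 0.75, 0.5625))
  # hand-computed weighted mean of (1, 2, 4) at these weights is 2.3
  expect_equal(unname(sc$matrix), diag(2) * 2.3, tolerance = 1e-12)
  expect_equal(sc$n_eff, 12L)
  expect_equal(sc$mode, "replicate_blocks")

  # single time point: self-normalizing
  d1 <- expression_ts(blocks[2], times = 0.3, center = FALSE)
  s1 <- smoothed_covariance(d1, 0, kernel_spec(bandwidth = 2))
  expect_equal(unname(s1$matrix), diag(2) * 2)

  # huge bandwidth: equal-weight average of the S_k
  sw <- smoothed_covariance(data, 0.5, kernel_spec(bandwidth = 1e8))
  expect_lt(max(abs(unname(sw$matrix) - diag(2) * mean(c(1, 2, 4)))), 1e-10)
})

test_that("replicate formula reduces to per-observation smoothing at n_k = 1", {
  set.seed(11)
  X <- matrix(rnorm(15), 5, 3)
  data <- expression_ts(X, times = 1:5, center = FALSE)
  spec <- kernel_spec(bandwidth = 1)
  sc <- smoothed_covariance(data, 0.25, spec)
  w <- compute_weights(data$time_points, 0.25, spec)
  direct <- Reduce(`+`, lapply(1:5, function(j)
    w[j] * tcrossprod(X[j, ]))) / sum(w)   # per-observation outer products
  expect_equal(unname(sc$matrix), direct, tolerance = 1e-12)
  expect_equal(sc$mode, "pooled_samples")
})

test_that("smoothed covariance is symmetric PSD over random datasets", {
  set.seed(23)
  for (r in 1:100) {
    N <- sample(2:6, 1); p <- sample(2:5, 1)
    blocks <- replicate(N, matrix(rnorm(p * sample(1:4, 1)), ncol = p),
                        simplify = FALSE)
    data <- expression_ts(blocks, times = sort(runif(N)) + (0:(N - 1)),
                          center = FALSE)
    sc <- smoothed_covariance(data, runif(1), kernel_spec(bandwidth = 2))
    expect_true(isSymmetric(sc$matrix, tol = 1e-12))
    expect_gt(min(eigen(sc$matrix, symmetric = TRUE,
                        only.values = TRUE)$values), -1e-10)
  }
})

test_that("weights are invariant to affine rescaling of raw time labels", {
  set.seed(5)
  blocks <- replicate(4, matrix(rnorm(8), 4, 2), simplify = FALSE)
  hours <- c(0, 2, 6, 20)
  d1 <- expression_ts(blocks, times = hours, center = FALSE)
  d2 <- expression_ts(blocks, times = 3 * hours + 7, center = FALSE)
  expect_equal(d1$time_points, d2$time_points)
  spec <- kernel_spec(bandwidth = 0.5)
  expect_equal(smoothed_covariance(d1, 0.3, spec)$matrix,
               smoothed_covariance(d2, 0.3, spec)$matrix)
})

test_that("tiny bandwidth with fallback isolates the nearest time point", {
  set.seed(9)
  blocks <- replicate(3, matrix(rnorm(12), 4, 3), simplify = FALSE)
  data <- expression_ts(blocks, times = c(0, 1, 2), center = FALSE)
  sc <- smoothed_covariance(data, data$time_points[2],
                            kernel_spec(bandwidth = 1e-4), fallback = TRUE)
  expect_equal(unname(sc$matrix), unname(per_time_covariance(blocks[[2]])))
})

test_that("expression_ts validates, centres, and orders blocks by time", {
  X <- matrix(1:12, 4, 3)
  d <- expression_ts(X, times = c(2, 1, 2, 1), center = TRUE)
  expect_equal(d$N, 2L)
  expect_equal(d$n_k, c(2L, 2L))
  expect_lt(max(abs(colMeans(do.call(rbind, d$blocks)))), 1e-10)
  expect_error(expression_ts(matrix(NA_real_, 2, 2), times = 1:2), "finite")
  expect_error(expression_ts(X, times = 1:3), "one entry per sample")
})
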