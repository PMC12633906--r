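# Independent oracles, kept deliberately separate from the package's
# algorithms: an ADMM solver for the penalized log-determinant objective
# (the package uses block coordinate descent), and a pair-by-pair
# enumeration of the classification metrics.

# ADMM for: min tr(Theta S) - log det Theta + sum_ij rho_ij |theta_ij|
admm_glasso <- function(S, Rho, rho = 1, iters = 20000, tol = 1e-10) {
  p <- nrow(S)
  if (length(Rho) == 1L) Rho <- matrix(Rho, p, p)
  Theta <- diag(p); Z <- diag(p); U <- matrix(0, p, p)
  for (it in seq_len(iters)) {
    eg <- eigen(rho * (Z - U) - S, symmetric = TRUE)
    d <- (eg$values + sqrt(eg$values^2 + 4 * rho)) / (2 * rho)
    Theta <- eg$vectors %*% (d * t(eg$vectors))
    Z_old <- Z
    A <- Theta + U
    Z <- sign(A) * pmax(abs(A) - Rho / rho, 0)
    U <- U + Theta - Z
    if (max(abs(Theta - Z)) < tol && max(abs(Z - Z_old)) < tol) break
  }
  (Z + t(Z)) / 2
}

# enumerate every unordered pair and recompute all eight metrics directly
brute_force_metrics <- function(est, true, p) {
  in_set <- function(e, i, j) {
    if (nrow(e) == 0L) return(FALSE)
    any((e[, 1L] == i & e[, 2L] == j) | (e[, 1L] == j & e[, 2L] == i))
  }
  TP <- FP <- TN <- FN <- 0L
  for (i in seq_len(p - 1L))
    for (j in seq.int(i + 1L, p)) {
      a <- in_set(est, i, j); b <- in_set(true, i, j)
      if (a && b) TP <- TP + 1L
      else if (a) FP <- FP + 1L
      else if (b) FN <- FN + 1L
      else TN <- TN + 1L
    }
  pre <- if (TP + FP == 0) 0 else TP / (TP + FP)
  tpr <- if (TP + FN == 0) 0 else TP / (TP + FN)
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  c(TP = TP, FP = FP, TN = TN, FN = FN,
    F1 = if (pre + tpr == 0) 0 else 2 * pre * tpr / (pre + tpr),
    FDR = if (TP + FP == 0) 0 else FP / (TP + FP),
    FPR = if (FP + TN == 0) 0 else FP / (FP + TN),
    MCC = if (den == 0) 0 else (TP * TN - FP * FN) / sqrt(den),
    precision = pre, TPR = tpr,
    jaccard = if (TP + FP + FN == 0) 1 else TP / (TP + FP + FN),
    edit_distance = FP + FN)
}

# random PD matrix with controllable conditioning
random_pd <- function(p, ridge = 0.5) {
  A <- matrix(rnorm(p * p), p)
  crossprod(A) / p + diag(p) * ridge
}

random_sym_penalty <- function(p, hi = 0.3) {
  R <- matrix(runif(p * p, 0, hi), p)
  (R + t(R)) / 2
}

random_edge_set <- function(p, prob = 0.3) {
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < prob
  pairs[keep, , drop = FALSE]
}

# expression series with known per-time covariance: blocks of 4 samples
# whose sample covariance is exactly diag(c, c)
diag_cov_block <- function(cc) {
  s <- sqrt(2 * cc)
  matrix(c(s, -s, 0, 0, 0, 0, s, -s), 4, 2)
}

# draw n obs from N(0, theta^-1)
draw_gaussian <- function(n, theta) {
  R <- chol(theta)
  t(backsolve(R, t(matrix(rnorm(n * nrow(theta)), n, nrow(theta)))))
}
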