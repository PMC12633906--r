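test_that("ba_graph builds preferential-attachment trees", {
  g <- ba_graph(2, 2, seed = 1)
  expect_equal(g$edges, matrix(c(1L, 2L), 1,
                               dimnames = list(NULL, c("i", "j"))))
  expect_equal(graph_degrees(g), c(1L, 1L))
  for (s in 1:5) {
    p <- sample(5:60, 1)
    g <- ba_graph(p, sample(c(2L, 4L), 1), seed = s)
    expect_equal(nrow(g$edges), p - 1L)
    expect_true(tvsfglasso:::.is_forest(g))
  }
  expect_error(ba_graph(10, 3), "2 or 4")
})

test_that("ba_graph degree distributions are right-skewed", {
  skewed <- vapply(1:50, function(s) {
    d <- graph_degrees(ba_graph(100, 2, seed = s))
    max(d) >= 3 * stats::median(d)
  }, TRUE)
  expect_gte(sum(skewed), 45)
})

test_that("superhub and Erdos-Renyi generators meet their contracts", {
  star <- superhub_graph(12, 1, bg_prob = 0, seed = 2)
  expect_equal(nrow(star$edges), 11L)
  expect_equal(max(graph_degrees(star)), 11L)

  hub2 <- superhub_graph(40, 2, seed = 3)
  expect_gte(min(graph_degrees(hub2)[1:2]), 5L)

  expect_equal(nrow(erdos_renyi_graph(20, 0, seed = 4)$edges), 0L)
  counts <- vapply(1:20, function(s)
    nrow(erdos_renyi_graph(100, 0.1, seed = s)$edges), 0L)
  expected <- 0.1 * choose(100, 2)
  sigma <- sqrt(expected * 0.9)
  expect_true(all(abs(counts - expected) <= 3 * sigma))
})

test_that("graph_to_precision is PD with support exactly on the edges", {
  expect_equal(unname(graph_to_precision(erdos_renyi_graph(5, 0))),
               0.1 * diag(5), ignore_attr = TRUE)

  one <- tvsfglasso:::.sim_graph(2, cbind(1, 2))
  th <- graph_to_precision(one, 0.3, seed = 5)
  expect_equal(sort(eigen(th, only.values = TRUE)$values), c(0.1, 0.7))

  for (s in 1:50) {
    g <- ba_graph(30, 2, seed = s)
    th <- graph_to_precision(g, 0.3, seed = s)
    expect_gte(min(eigen(th, symmetric = TRUE, only.values = TRUE)$values),
               0.1 - 1e-12)
    supp <- which(abs(th) > 0 & upper.tri(th), arr.ind = TRUE)
    expect_setequal(tvsfglasso:::.edge_keys(supp),
                    tvsfglasso:::.edge_keys(g$edges))
  }
})

test_that("sign persistence reuses recorded signs for surviving edges", {
  g <- ba_graph(10, 2, seed = 6)
  th1 <- graph_to_precision(g, 0.3, seed = 7)
  signs <- attr(th1, "signs")
  th2 <- graph_to_precision(g, 0.3, seed = 8, signs = signs)
  expect_equal(th1, th2, ignore_attr = TRUE)
})

test_that("evolve_graph preserves edge count, acyclicity and skew", {
  g <- ba_graph(50, 2, seed = 9)
  expect_identical(evolve_graph(g, 0, seed = 1)$edges, g$edges)

  set.seed(10)
  cur <- ba_graph(100, 2)
  ratio_ok <- 0
  for (s in 1:200) {
    cur <- evolve_graph(cur, 1)
    expect_equal(nrow(cur$edges), 99L)
    expect_true(tvsfglasso:::.is_forest(cur))
    d <- graph_degrees(cur)
    if (max(d) >= 3 * stats::median(d)) ratio_ok <- ratio_ok + 1
  }
  expect_gte(ratio_ok, 160)   # skew retained in >= 80% of steps
})

test_that("simulate_dynamic_truth meets the module contracts", {
  # degenerate cases
  t1 <- simulate_dynamic_truth(simulation_spec("ba_huge", p = 10, N = 1,
                                               n_k = 2, seed = 11))
  expect_equal(length(t1$precisions), 1L)
  t0 <- simulate_dynamic_truth(simulation_spec("ba_huge", p = 10, N = 4,
                                               n_k = 2, change_rate = 0,
                                               seed = 12))
  for (k in 2:4) expect_equal(t0$precisions[[k]], t0$precisions[[1]])

  # every generator: PD precisions with support exactly the edge set
  for (gen in c("ba_huge", "ba_liu_ihler", "ba_smooth", "superhub",
                "yang_peng_abrupt", "erdos_renyi")) {
    tr <- simulate_dynamic_truth(simulation_spec(gen, p = 20, N = 8,
                                                 n_k = 2, seed = 13))
    for (k in 1:8) {
      th <- tr$precisions[[k]]
      expect_gt(min(eigen(th, symmetric = TRUE, only.values = TRUE)$values),
                0)
      supp <- which(abs(th) >= 1e-8 & upper.tri(th), arr.ind = TRUE)
      expect_setequal(tvsfglasso:::.edge_keys(supp),
                      tvsfglasso:::.edge_keys(edge_set(tr$graphs, k)))
    }
  }
})

test_that("consecutive edge sets stay nearly identical at change_rate 1", {
  tr <- simulate_dynamic_truth(simulation_spec("ba_huge", p = 100, N = 30,
                                               n_k = 1, change_rate = 1,
                                               seed = 14))
  jac <- vapply(1:29, function(k) {
    a <- tvsfglasso:::.edge_keys(edge_set(tr$graphs, k))
    b <- tvsfglasso:::.edge_keys(edge_set(tr$graphs, k + 1))
    length(intersect(a, b)) / length(union(a, b))
  }, 0)
  expect_gte(mean(jac), 0.95)
})

test_that("the abrupt generator rewires a block at one interior time", {
  tr <- simulate_dynamic_truth(simulation_spec("yang_peng_abrupt", p = 40,
                                               N = 10, n_k = 2,
                                               change_rate = 0.5,
                                               seed = 15))
  ed <- vapply(1:9, function(k) {
    dg <- difference_graph(tr$graphs, k)
    nrow(dg$added) + nrow(dg$removed)
  }, 0)
  expect_gte(max(ed), 0.4 * nrow(edge_set(tr$graphs, 1)))  # the shock
  expect_lte(stats::median(ed), 4)                          # normal steps
})

test_that("sample_timeseries draws the requested blocks reproducibly", {
  tr <- simulate_dynamic_truth(simulation_spec("ba_huge", p = 6, N = 3,
                                               n_k = 4, seed = 16))
  d1 <- sample_timeseries(tr, seed = 17)
  expect_equal(d1$n_k, rep(4L, 3))
  expect_equal(d1$p, 6L)
  d2 <- sample_timeseries(tr, seed = 17)
  expect_identical(d1$blocks, d2$blocks)

  # Monte-Carlo: sample covariance approaches Theta^-1
  tr1 <- simulate_dynamic_truth(simulation_spec("ba_huge", p = 4, N = 1,
                                                n_k = 1, seed = 18))
  big <- sample_timeseries(tr1, n_k = 1e5, seed = 19)
  S <- per_time_covariance(big$blocks[[1]])
  Sigma <- solve(tr1$precisions[[1]])
  # Monte-Carlo error scales with the covariance magnitude (entries of
  # Sigma reach ~5 here), so the 0.02 band is relative to that scale
  expect_lt(max(abs(S - Sigma)), 0.02 * max(1, max(abs(Sigma))))
})
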