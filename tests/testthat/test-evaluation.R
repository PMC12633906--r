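test_that("confusion counts enumerate unordered pairs", {
  e <- rbind(c(1, 2), c(1, 3))
  expect_equal(confusion_counts(e, e, 10),
               c(TP = 2L, FP = 0L, TN = 43L, FN = 0L))
  empty <- matrix(integer(0), ncol = 2)
  e5 <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6))
  expect_equal(confusion_counts(empty, e5, 10),
               c(TP = 0L, FP = 0L, TN = 40L, FN = 5L))
  expect_equal(confusion_counts(rbind(c(1, 2), c(1, 4)),
                                rbind(c(1, 2), c(1, 3)), 4),
               c(TP = 1L, FP = 1L, TN = 3L, FN = 1L))
  expect_error(confusion_counts(rbind(c(1, 9)), e, 4), "outside")
})

test_that("edge_metrics matches direct substitution and conventions", {
  m <- edge_metrics(1, 1, 3, 1)
  expect_equal(unname(m[c("precision", "TPR", "FDR", "FPR")]),
               c(0.5, 0.5, 0.5, 0.25))
  expect_equal(unname(m[c("F1", "jaccard", "MCC", "edit_distance")]),
               c(0.5, 1 / 3, 0.25, 2))

  perfect <- edge_metrics(7, 0, 38, 0)
  expect_equal(unname(perfect[c("F1", "MCC", "jaccard")]), c(1, 1, 1))
  expect_equal(unname(perfect[c("FDR", "FPR", "edit_distance")]), c(0, 0, 0))

  none <- edge_metrics(0, 0, 45, 0)     # both graphs empty
  expect_equal(unname(none[c("precision", "FDR", "MCC", "jaccard")]),
               c(0, 0, 0, 1))
  expect_error(edge_metrics(-1, 0, 0, 0), "nonnegative")
})

test_that("edit distance is a metric on edge sets", {
  set.seed(111)
  ed <- function(a, b, p) unname(
    edge_metrics(confusion_counts(a, b, p))["edit_distance"])
  for (r in 1:25) {
    p <- sample(4:8, 1)
    A <- random_edge_set(p); B <- random_edge_set(p); C <- random_edge_set(p)
    expect_equal(ed(A, A, p), 0)
    expect_equal(ed(A, B, p), ed(B, A, p))
    expect_lte(ed(A, C, p), ed(A, B, p) + ed(B, C, p))
  }
})

test_that("evaluate_networks reports per-time rows and time averages", {
  tr <- simulate_dynamic_truth(simulation_spec("ba_huge", p = 8, N = 3,
                                               n_k = 2, seed = 121))
  est <- tr$graphs                      # estimate == truth
  rep <- evaluate_networks(est, tr)
  expect_equal(nrow(rep), 3L)
  expect_equal(unname(attr(rep, "means")[c("F1", "MCC")]), c(1, 1))
  expect_true(all(rep$TP + rep$FP + rep$TN + rep$FN == choose(8, 2)))
})

test_that("degree trajectories cover static, empty and isolated cases", {
  edges <- list(rbind(c(1, 2), c(2, 3)), rbind(c(1, 2), c(2, 3)))
  net <- dynamic_network(paste0("n", 1:4), c(0, 1), edges)
  traj <- degree_trajectories(net)
  expect_equal(traj, matrix(c(1, 2, 1, 0, 1, 2, 1, 0), 4,
                            dimnames = list(paste0("n", 1:4), NULL)))
  empty_net <- dynamic_network(paste0("n", 1:3), c(0, 1),
                               list(matrix(integer(0), ncol = 2),
                                    matrix(integer(0), ncol = 2)))
  expect_true(all(degree_trajectories(empty_net) == 0))
})

test_that("degree slopes agree with the least-squares oracle", {
  tt <- c(0, 0.25, 0.5, 0.75, 1)
  traj <- rbind(const = rep(3, 5), linear = tt, noisy = c(0, 1, 0, 2, 1))
  out <- degree_slopes(traj, tt, top_k = 3)
  expect_equal(out$slope[out$node == "const"], 0)
  expect_equal(out$slope[out$node == "linear"], 1)
  set.seed(131)
  traj_r <- matrix(rpois(40, 3), 8, 5,
                   dimnames = list(paste0("n", 1:8), NULL))
  res <- degree_slopes(traj_r, tt, top_k = 8)
  for (i in 1:8) {
    fit <- lm(traj_r[res$node[i], ] ~ tt)
    expect_equal(res$slope[i], unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(res$intercept[i], unname(coef(fit)[1]), tolerance = 1e-10)
  }
  expect_equal(nrow(degree_slopes(traj_r, tt, top_k = 3)), 3L)
})

test_that("neighborhood and difference graphs follow their definitions", {
  edges <- list(rbind(c(1, 2), c(2, 3), c(4, 5)),
                rbind(c(1, 2), c(3, 4), c(4, 5)))
  net <- dynamic_network(paste0("n", 1:6), c(0, 1), edges)

  nb <- neighborhood(net, "n2", 1)
  expect_equal(nb$nodes, c("n1", "n2", "n3"))
  expect_equal(nrow(nb$edges), 2L)
  iso <- neighborhood(net, "n6", 1)
  expect_equal(iso$nodes, "n6")
  expect_equal(nrow(iso$edges), 0L)
  expect_equal(neighborhood(net, "n1", 2)$nodes, c("n1", "n2"))
  # radius 2 walks one step further
  expect_equal(neighborhood(net, "n1", 1, radius = 2)$nodes,
               c("n1", "n2", "n3"))

  dg <- difference_graph(net, 1)
  expect_equal(dg$added, matrix(c(3L, 4L), 1,
                                dimnames = list(NULL, c("i", "j"))))
  expect_equal(dg$removed, matrix(c(2L, 3L), 1,
                                  dimnames = list(NULL, c("i", "j"))))
  cc <- confusion_counts(edges[[1]], edges[[2]], 5)
  expect_equal(nrow(dg$added) + nrow(dg$removed),
               unname(edge_metrics(cc)["edit_distance"]))

  same <- dynamic_network(paste0("n", 1:5), c(0, 1),
                          list(edges[[1]], edges[[1]]))
  d0 <- difference_graph(same, 1)
  expect_equal(nrow(d0$added) + nrow(d0$removed), 0L)
})
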