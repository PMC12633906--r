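# Dynamic-network simulators. Graphs are stored as lists
# list(p = <int>, edges = <m x 2 integer matrix, i < j>) of class
# "sim_graph". Precision matrices are built by assigning signed weights to
# edges and making the diagonal strictly dominant, so positive definiteness
# holds by the Gershgorin bound and the support equals the edge set exactly.

.sim_graph <- function(p, edges) {
  e <- matrix(as.integer(edges), ncol = 2L,
              dimnames = list(NULL, c("i", "j")))
  if (nrow(e) > 0L) {
    swap <- e[, 1L] > e[, 2L]
    e[swap, ] <- e[swap, 2:1]
    e <- unique(e[order(e[, 1L], e[, 2L]), , drop = FALSE])
  }
  structure(list(p = as.integer(p), edges = e), class = "sim_graph")
}

#' @export
print.sim_graph <- function(x, ...) {
  cat(sprintf("Graph: %d nodes, %d edges, max degree %d\n",
              x$p, nrow(x$edges),
              if (nrow(x$edges)) max(graph_degrees(x)) else 0L))
  invisible(x)
}

#' Node degrees of a simulated graph
#' @param graph A `sim_graph`.
#' @return Integer vector of length `p`.
#' @export
graph_degrees <- function(graph) {
  tabulate(graph$edges, nbins = graph$p)
}

# connected-component labels (union-find)
.components <- function(p, edges) {
  parent <- seq_len(p)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges) > 0L)
    for (r in seq_len(nrow(edges))) {
      a <- find(edges[r, 1L]); b <- find(edges[r, 2L])
      if (a != b) parent[a] <- b
    }
  vapply(seq_len(p), find, 1L)
}

.is_forest <- function(graph) {
  comp <- .components(graph$p, graph$edges)
  # a graph is a forest iff edges = nodes - components
  nrow(graph$edges) == graph$p - length(unique(comp))
}

#' Barabasi-Albert preferential-attachment tree
#'
#' Seed nodes are connected as a path; each subsequent node attaches to one
#' existing node with probability proportional to its current degree. The
#' result is a tree (`p - 1` edges, acyclic) with a right-skewed degree
#' distribution.
#'
#' @param p Number of nodes (`p > init_nodes`, or `p == init_nodes`).
#' @param init_nodes Seed nodes, 2 or 4.
#' @param seed Optional RNG seed.
#' @return A `sim_graph`.
#' @export
ba_graph <- function(p, init_nodes = 2L, seed = NULL) {
  if (!init_nodes %in% c(2L, 4L)) .stop_arg("`init_nodes` must be 2 or 4")
  if (p < init_nodes) .stop_arg("`p` must be >= `init_nodes`")
  if (!is.null(seed)) set.seed(seed)
  edges <- cbind(seq_len(init_nodes - 1L), seq_len(init_nodes - 1L) + 1L)
  deg <- tabulate(edges, nbins = p)
  if (p > init_nodes)
    for (v in seq.int(init_nodes + 1L, p)) {
      existing <- seq_len(v - 1L)
      target <- sample(existing, 1L, prob = deg[existing] + (deg[existing] == 0))
      edges <- rbind(edges, c(target, v))
      deg[target] <- deg[target] + 1L
      deg[v] <- 1L
    }
  .sim_graph(p, edges)
}

#' Super-hub graph
#'
#' `n_hubs` hub nodes each connect to a disjoint random share of the
#' remaining nodes (a union of stars), plus sparse background edges among
#' the non-hub nodes.
#'
#' @param p Number of nodes.
#' @param n_hubs Number of hubs (`1 <= n_hubs < p`).
#' @param bg_prob Probability of each background non-hub pair. Default 0.01.
#' @param seed Optional RNG seed.
#' @return A `sim_graph`.
#' @export
superhub_graph <- function(p, n_hubs = 2L, bg_prob = 0.01, seed = NULL) {
  if (n_hubs < 1L || n_hubs >= p) .stop_arg("need 1 <= n_hubs < p")
  if (!is.null(seed)) set.seed(seed)
  hubs <- seq_len(n_hubs)
  rest <- seq.int(n_hubs + 1L, p)
  assign <- sample(hubs, length(rest), replace = TRUE)
  edges <- cbind(assign, rest)
  if (bg_prob > 0 && length(rest) > 1L) {
    pairs <- utils::combn(rest, 2L)
    keep <- runif(ncol(pairs)) < bg_prob
    if (any(keep)) edges <- rbind(edges, t(pairs[, keep, drop = FALSE]))
  }
  .sim_graph(p, edges)
}

#' Erdos-Renyi graph
#'
#' @param p Number of nodes.
#' @param edge_prob Independent probability of each of the `p(p-1)/2` pairs.
#' @param seed Optional RNG seed.
#' @return A `sim_graph`.
#' @export
erdos_renyi_graph <- function(p, edge_prob, seed = NULL) {
  if (edge_prob < 0 || edge_prob > 1) .stop_arg("`edge_prob` not in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < edge_prob
  .sim_graph(p, pairs[keep, , drop = FALSE])
}

#' Precision matrix with support exactly on a graph's edges
#'
#' Off-diagonal entries are `+/- edge_weight` (random signs, or signs
#' supplied for persisting edges); the diagonal is the row sum of absolute
#' off-diagonal entries plus `diag_slack`, making the matrix strictly
#' diagonally dominant and hence positive definite with minimum eigenvalue
#' at least `diag_slack`.
#'
#' @param graph A `sim_graph`.
#' @param edge_weight Base partial-covariance magnitude. Default 0.3.
#' @param seed Optional RNG seed for the signs.
#' @param signs Optional named vector (`"i-j"` keys) of `+/- 1` signs to
#'   reuse; missing edges get fresh random signs.
#' @param diag_slack Diagonal dominance margin. Default 0.1.
#' @return A `p x p` positive definite matrix whose nonzero off-diagonal
#'   pattern equals the edge set exactly.
#' @export
graph_to_precision <- function(graph, edge_weight = 0.3, seed = NULL,
                               signs = NULL, diag_slack = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  p <- graph$p
  e <- graph$edges
  theta <- matrix(0, p, p)
  if (nrow(e) > 0L) {
    keys <- .edge_keys(e)
    sgn <- if (is.null(signs)) rep(NA_real_, nrow(e)) else unname(signs[keys])
    fresh <- is.na(sgn)
    sgn[fresh] <- sample(c(-1, 1), sum(fresh), replace = TRUE)
    for (r in seq_len(nrow(e))) {
      w <- sgn[r] * edge_weight
      theta[e[r, 1L], e[r, 2L]] <- w
      theta[e[r, 2L], e[r, 1L]] <- w
    }
    attr(theta, "signs") <- stats::setNames(sgn, keys)
  } else attr(theta, "signs") <- stats::setNames(numeric(0), character(0))
  diag(theta) <- rowSums(abs(theta)) + diag_slack
  theta
}

#' One evolution step of a dynamic graph
#'
#' Draws `d ~ Poisson(change_rate)` edge changes. Each change deletes an
#' edge sampled with probability proportional to `1 / (deg_i + deg_j)`
#' (low-degree edges change more often) and re-attaches the lower-degree
#' endpoint to a node sampled proportionally to degree (preferential
#' attachment), rejecting self-loops, duplicate edges and — on forests —
#' cycles. Edge count is preserved; trees stay trees; the degree skew is
#' maintained in expectation.
#'
#' @param graph A `sim_graph`.
#' @param change_rate Expected number of edge changes. Default 1.
#' @param seed Optional RNG seed.
#' @return The evolved `sim_graph`.
#' @export
evolve_graph <- function(graph, change_rate = 1, seed = NULL) {
  if (change_rate < 0) .stop_arg("`change_rate` must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  d <- rpois(1L, change_rate)
  if (d == 0L || nrow(graph$edges) == 0L) return(graph)
  p <- graph$p
  edges <- graph$edges
  forest <- .is_forest(graph)
  for (step in seq_len(d)) {
    deg <- tabulate(edges, nbins = p)
    w_del <- 1 / (deg[edges[, 1L]] + deg[edges[, 2L]])
    del <- sample.int(nrow(edges), 1L, prob = w_del)
    u <- edges[del, 1L]; v <- edges[del, 2L]
    orphan <- if (deg[u] < deg[v]) u else if (deg[v] < deg[u]) v
              else sample(c(u, v), 1L)
    rest <- edges[-del, , drop = FALSE]
    deg2 <- tabulate(rest, nbins = p)
    comp <- if (forest) .components(p, rest) else NULL
    adj_orphan <- unique(c(rest[rest[, 1L] == orphan, 2L],
                           rest[rest[, 2L] == orphan, 1L]))
    ok <- setdiff(seq_len(p), c(orphan, adj_orphan))
    if (forest) ok <- ok[comp[ok] != comp[orphan]]
    if (length(ok) == 0L) next   # no legal rewiring; keep the edge
    target <- if (length(ok) == 1L) ok else
      sample(ok, 1L, prob = deg2[ok] + 1)
    edges <- rbind(rest, c(min(orphan, target), max(orphan, target)))
  }
  .sim_graph(p, edges)
}

#' Simulation scenario specification
#'
#' @param generator One of `"ba_huge"`, `"ba_liu_ihler"` (preferential
#'   attachment trees, 2 seed nodes), `"ba_smooth"` (4 seed nodes, smoothly
#'   interpolated precisions), `"superhub"`, `"yang_peng_abrupt"` (one
#'   abrupt block-rewiring shock), `"erdos_renyi"`.
#' @param p Node count (>= 4).
#' @param N Number of time points (>= 1).
#' @param n_k Replicates per time point (>= 1).
#' @param change_rate Expected edge changes per step. Default 1.
#' @param edge_weight Base partial-covariance magnitude. Default 0.3.
#' @param seed RNG seed (the whole simulation is reproducible from it).
#' @param n_hubs Hubs for `"superhub"`. Default 2.
#' @param edge_prob Pair probability for the Erdos-Renyi generators;
#'   default `2 / (p - 1)` (expected degree 2).
#' @param smooth_span Anchor spacing (time steps) for `"ba_smooth"`
#'   interpolation. Default 5.
#' @param shock_frac Fraction of edges rewired by the abrupt shock.
#'   Default 0.3.
#' @return An object of class `sim_spec`.
#' @export
simulation_spec <- function(generator = c("ba_huge", "ba_liu_ihler",
                                          "ba_smooth", "superhub",
                                          "yang_peng_abrupt",
                                          "erdos_renyi"),
                            p = 100L, N = 10L, n_k = 10L, change_rate = 1,
                            edge_weight = 0.3, seed = 1L, n_hubs = 2L,
                            edge_prob = NULL, smooth_span = 5L,
                            shock_frac = 0.3) {
  generator <- match.arg(generator)
  if (p < 4L) .stop_arg("`p` must be >= 4")
  if (N < 1L) .stop_arg("`N` must be >= 1")
  if (n_k < 1L) .stop_arg("`n_k` must be >= 1")
  if (change_rate < 0) .stop_arg("`change_rate` must be nonnegative")
  if (is.null(edge_prob)) edge_prob <- 2 / (p - 1)
  structure(list(generator = generator, p = as.integer(p),
                 N = as.integer(N), n_k = as.integer(n_k),
                 change_rate = change_rate, edge_weight = edge_weight,
                 seed = as.integer(seed), n_hubs = as.integer(n_hubs),
                 edge_prob = edge_prob, smooth_span = as.integer(smooth_span),
                 shock_frac = shock_frac),
            class = "sim_spec")
}

# abrupt shock: rewire a fraction of edges uniformly at random
.shock_graph <- function(graph, frac) {
  m <- nrow(graph$edges)
  n_change <- max(1L, round(frac * m))
  edges <- graph$edges
  drop <- sample.int(m, n_change)
  edges <- edges[-drop, , drop = FALSE]
  keys <- .edge_keys(edges)
  added <- 0L
  while (added < n_change) {
    cand <- sort(sample.int(graph$p, 2L))
    key <- paste(cand[1L], cand[2L], sep = "-")
    if (!key %in% keys) {
      edges <- rbind(edges, cand)
      keys <- c(keys, key)
      added <- added + 1L
    }
  }
  .sim_graph(graph$p, edges)
}

#' Simulate a dynamic ground truth
#'
#' Builds the initial graph with the requested generator, evolves it over
#' `N` time points (few changes per step, degree skew and acyclicity
#' preserved for the tree-based modes; one abrupt shock for
#' `"yang_peng_abrupt"`), and attaches a positive definite precision matrix
#' whose support equals the edge set at each time point. Edge signs persist
#' while an edge persists. For `"ba_smooth"`, graphs evolve at anchor time
#' points and the precision entries are interpolated linearly in between
#' (a convex combination of positive definite matrices, hence positive
#' definite); the per-time edge set is the support of the interpolated
#' precision.
#'
#' @param spec A [simulation_spec()].
#' @return An object of class `dynamic_truth`: `graphs` (a
#'   [dynamic_network()]), `precisions` (list of PD matrices), `provenance`
#'   (the spec).
#' @export
simulate_dynamic_truth <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  p <- spec$p; N <- spec$N

  g0 <- switch(spec$generator,
    ba_huge = ba_graph(p, 2L),
    ba_liu_ihler = ba_graph(p, 2L),
    ba_smooth = ba_graph(p, 4L),
    superhub = superhub_graph(p, spec$n_hubs),
    yang_peng_abrupt = erdos_renyi_graph(p, spec$edge_prob),
    erdos_renyi = erdos_renyi_graph(p, spec$edge_prob))

  signs <- stats::setNames(numeric(0), character(0))
  mk_theta <- function(g) {
    th <- graph_to_precision(g, edge_weight = spec$edge_weight,
                             signs = signs)
    keys <- .edge_keys(g$edges)
    signs <<- attr(th, "signs")[keys]   # drop signs of deleted edges
    th
  }

  precisions <- vector("list", N)
  graphs <- vector("list", N)

  if (spec$generator == "ba_smooth" && N > 1L) {
    span <- max(1L, spec$smooth_span)
    anchors_idx <- unique(c(seq(1L, N, by = span), N))
    g <- g0
    anchor_theta <- list()
    for (a in seq_along(anchors_idx)) {
      if (a > 1L) {
        steps <- anchors_idx[a] - anchors_idx[a - 1L]
        for (s in seq_len(steps)) g <- evolve_graph(g, spec$change_rate)
      }
      anchor_theta[[a]] <- mk_theta(g)
    }
    for (k in seq_len(N)) {
      a <- findInterval(k, anchors_idx)
      if (a >= length(anchors_idx)) {
        th <- anchor_theta[[length(anchors_idx)]]
      } else {
        lo <- anchors_idx[a]; hi <- anchors_idx[a + 1L]
        w <- (k - lo) / (hi - lo)
        th <- (1 - w) * anchor_theta[[a]] + w * anchor_theta[[a + 1L]]
      }
      attr(th, "signs") <- NULL
      precisions[[k]] <- th
      supp <- which(abs(th) >= .EDGE_ZERO_TOL & upper.tri(th),
                    arr.ind = TRUE)
      graphs[[k]] <- .sim_graph(p, supp)
    }
  } else {
    g <- g0
    shock_at <- if (spec$generator == "yang_peng_abrupt" && N > 2L)
      sample(seq.int(2L, N - 1L), 1L) else -1L
    for (k in seq_len(N)) {
      if (k > 1L) {
        g <- if (k == shock_at) .shock_graph(g, spec$shock_frac)
             else evolve_graph(g, spec$change_rate)
      }
      th <- mk_theta(g)
      attr(th, "signs") <- NULL
      precisions[[k]] <- th
      graphs[[k]] <- g
    }
  }

  time_points <- if (N == 1L) 0 else seq(0, 1, length.out = N)
  net <- dynamic_network(paste0("g", seq_len(p)), time_points,
                         lapply(graphs, function(g) g$edges),
                         params = list(generator = spec$generator,
                                       seed = spec$seed))
  structure(list(graphs = net, precisions = precisions, provenance = spec),
            class = "dynamic_truth")
}

#' @export
print.dynamic_truth <- function(x, ...) {
  cat(sprintf("Dynamic truth (%s): %d nodes, %d time points\n",
              x$provenance$generator, x$graphs$p, x$graphs$N))
  invisible(x)
}

#' Draw Gaussian time-series replicates from a dynamic truth
#'
#' At each time point `t_k`, draws `n_k` independent observations from
#' `N(0, Theta(t_k)^{-1})` (observations are independent over time). Time
#' labels are equally spaced in `[0, 1]`.
#'
#' @param truth A [simulate_dynamic_truth()] result.
#' @param n_k Replicates per time point; defaults to the spec's value.
#' @param seed Optional RNG seed.
#' @param center Centre genes over all observations (see
#'   [expression_ts()]). Default `FALSE` to preserve the exact draws; the
#'   population mean is zero by construction.
#' @return An [expression_ts()] object.
#' @export
sample_timeseries <- function(truth, n_k = NULL, seed = NULL,
                              center = FALSE) {
  stopifnot(inherits(truth, "dynamic_truth"))
  if (is.null(n_k)) n_k <- truth$provenance$n_k
  if (n_k < 1L) .stop_arg("`n_k` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  p <- truth$graphs$p
  blocks <- lapply(truth$precisions, function(theta) {
    R <- chol(theta)                       # theta = R'R, cov = R^-1 R^-T
    Z <- matrix(rnorm(n_k * p), n_k, p)
    t(backsolve(R, t(Z)))
  })
  expression_ts(blocks, times = truth$graphs$time_points,
                gene_ids = truth$graphs$node_ids, center = center)
}
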