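# Binary-classification / structure metrics over edge sets, and the
# degree-trajectory analytics for dynamic networks.

.edges_arg <- function(x, k = NULL) {
  if (inherits(x, "dyn_net")) {
    if (is.null(k)) .stop_arg("time index required for a dynamic network")
    return(edge_set(x, k))
  }
  if (inherits(x, "sim_graph")) return(x$edges)
  e <- matrix(as.integer(x), ncol = 2L)
  e
}

#' Confusion counts between two edge sets
#'
#' Counts over all `p(p-1)/2` unordered node pairs.
#'
#' @param estimated,true Two-column edge matrices (or `sim_graph`s) over the
#'   same `p` nodes, no self-loops.
#' @param p Number of nodes.
#' @return Named integer vector `(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(estimated, true, p) {
  est <- .edges_arg(estimated); tru <- .edges_arg(true)
  if (nrow(est) && max(est) > p || nrow(tru) && max(tru) > p)
    .stop_arg("edge references a node outside 1..p")
  ek <- .edge_keys(est); tk <- .edge_keys(tru)
  TP <- length(intersect(ek, tk))
  FP <- length(setdiff(ek, tk))
  FN <- length(setdiff(tk, ek))
  p <- as.integer(p)
  TN <- (p * (p - 1L)) %/% 2L - TP - FP - FN
  c(TP = TP, FP = FP, TN = TN, FN = FN)
}

#' The eight evaluation metrics from confusion counts
#'
#' Precision, TPR (recall), FDR, FPR, F1, Jaccard index, Matthews
#' correlation coefficient, and graph edit distance (`FP + FN`: edge
#' insertions plus deletions over a fixed node set). Zero-denominator
#' conventions: precision and FDR are 0 when no edge is predicted, F1 is 0
#' when precision + TPR = 0, MCC is 0 when any factor of its denominator is
#' 0, and the Jaccard index is 1 when both edge sets are empty.
#'
#' @param TP,FP,TN,FN Nonnegative confusion counts (or a single named
#'   vector as returned by [confusion_counts()] passed as `TP`).
#' @return Named numeric vector with elements `F1, FDR, FPR, MCC,
#'   precision, TPR, jaccard, edit_distance`.
#' @export
edge_metrics <- function(TP, FP = NULL, TN = NULL, FN = NULL) {
  if (is.null(FP) && length(TP) == 4L) {
    cc <- TP; TP <- cc[["TP"]]; FP <- cc[["FP"]]
    TN <- cc[["TN"]]; FN <- cc[["FN"]]
  }
  if (any(c(TP, FP, TN, FN) < 0)) .stop_arg("counts must be nonnegative")
  # double arithmetic: the MCC denominator overflows 32-bit integers
  TP <- as.numeric(TP); FP <- as.numeric(FP)
  TN <- as.numeric(TN); FN <- as.numeric(FN)
  pre <- if (TP + FP == 0) 0 else TP / (TP + FP)
  fdr <- if (TP + FP == 0) 0 else FP / (TP + FP)
  tpr <- if (TP + FN == 0) 0 else TP / (TP + FN)
  fpr <- if (FP + TN == 0) 0 else FP / (FP + TN)
  f1 <- if (pre + tpr == 0) 0 else 2 * pre * tpr / (pre + tpr)
  ji <- if (TP + FP + FN == 0) 1 else TP / (TP + FP + FN)
  denom <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom == 0) 0 else
    (TP * TN - FP * FN) / sqrt(denom)
  c(F1 = f1, FDR = fdr, FPR = fpr, MCC = mcc, precision = pre,
    TPR = tpr, jaccard = ji, edit_distance = FP + FN)
}

#' Evaluate an estimated dynamic network against the truth
#'
#' @param estimated A [dynamic_network()] (or `pooled_fit`, evaluated
#'   against every time point of the truth).
#' @param truth A [dynamic_network()] or `dynamic_truth`.
#' @return A `metrics_report`: data frame with one row per time point
#'   (confusion counts and the eight metrics) plus a `means` attribute of
#'   time-averaged metrics.
#' @export
evaluate_networks <- function(estimated, truth) {
  if (inherits(truth, "dynamic_truth")) truth <- truth$graphs
  stopifnot(inherits(truth, "dyn_net"))
  p <- truth$p
  get_est <- if (inherits(estimated, "pooled_fit")) {
    function(k) estimated$edges
  } else {
    stopifnot(inherits(estimated, "dyn_net"))
    if (estimated$N != truth$N)
      .stop_arg("estimate and truth have different numbers of time points")
    function(k) edge_set(estimated, k)
  }
  rows <- lapply(seq_len(truth$N), function(k) {
    cc <- confusion_counts(get_est(k), edge_set(truth, k), p)
    c(time = truth$time_points[k], cc, edge_metrics(cc))
  })
  df <- as.data.frame(do.call(rbind, rows))
  metric_cols <- c("F1", "FDR", "FPR", "MCC", "precision", "TPR",
                   "jaccard", "edit_distance")
  structure(df, means = colMeans(df[, metric_cols, drop = FALSE]),
            class = c("metrics_report", "data.frame"))
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Per-time-point network recovery metrics\n")
  print.data.frame(x, digits = 3)
  cat("\nTime-averaged:\n")
  print(round(attr(x, "means"), 3))
  invisible(x)
}

#' Per-node degree over time
#'
#' @param network A [dynamic_network()].
#' @return `p x N` integer matrix; rows are nodes (named), columns time
#'   points.
#' @export
degree_trajectories <- function(network) {
  stopifnot(inherits(network, "dyn_net"))
  out <- vapply(network$edges,
                function(e) tabulate(e, nbins = network$p),
                integer(network$p))
  out <- matrix(out, nrow = network$p,
                dimnames = list(network$node_ids, NULL))
  out
}

#' Rank nodes by the slope of their degree trajectory
#'
#' Fits an ordinary least-squares line `degree_i = b0 + b1 * time` per node
#' and returns the nodes with the largest slopes (the nodes whose
#' connectivity grows fastest over the series).
#'
#' @param trajectories `p x N` degree matrix from [degree_trajectories()].
#' @param time_points Time values (length N).
#' @param top_k Number of top nodes to keep. Default 5.
#' @return Data frame with columns `node`, `slope`, `intercept`, sorted by
#'   slope (descending), first `top_k` rows.
#' @export
degree_slopes <- function(trajectories, time_points, top_k = 5L) {
  tt <- as.numeric(time_points)
  if (length(tt) != ncol(trajectories))
    .stop_arg("`time_points` must match the trajectory columns")
  tc <- tt - mean(tt)
  sxx <- sum(tc^2)
  slopes <- if (sxx == 0) rep(0, nrow(trajectories)) else
    as.numeric(trajectories %*% tc) / sxx
  intercepts <- rowMeans(trajectories) - slopes * mean(tt)
  ord <- order(slopes, decreasing = TRUE)
  out <- data.frame(node = rownames(trajectories)[ord],
                    slope = slopes[ord], intercept = intercepts[ord],
                    stringsAsFactors = FALSE)
  utils::head(out, top_k)
}

#' Neighbourhood subgraph of a node at one time point
#'
#' @param network A [dynamic_network()].
#' @param node Node id (character) or index.
#' @param k Time index.
#' @param radius Neighbourhood radius (graph distance). Default 1.
#' @return List with `nodes` (ids, including the centre) and `edges`
#'   (induced edge matrix).
#' @export
neighborhood <- function(network, node, k, radius = 1L) {
  stopifnot(inherits(network, "dyn_net"))
  if (is.character(node)) node <- match(node, network$node_ids)
  if (is.na(node) || node < 1L || node > network$p)
    .stop_arg("unknown node")
  e <- edge_set(network, k)
  keep <- node
  frontier <- node
  for (r in seq_len(radius)) {
    nb <- c(e[e[, 1L] %in% frontier, 2L], e[e[, 2L] %in% frontier, 1L])
    frontier <- setdiff(nb, keep)
    keep <- union(keep, frontier)
    if (length(frontier) == 0L) break
  }
  sub <- e[e[, 1L] %in% keep & e[, 2L] %in% keep, , drop = FALSE]
  list(nodes = network$node_ids[sort(keep)], edges = sub)
}

#' Difference graph between consecutive time points
#'
#' @param network A [dynamic_network()].
#' @param k Time index; the comparison is `E(t_{k+1})` versus `E(t_k)`.
#' @return List with `added` and `removed` edge matrices. Their total row
#'   count equals the graph edit distance between the two edge sets.
#' @export
difference_graph <- function(network, k) {
  stopifnot(inherits(network, "dyn_net"))
  if (k < 1L || k >= network$N)
    .stop_arg("`k` must be between 1 and N - 1")
  a <- .edge_keys(edge_set(network, k))
  b <- .edge_keys(edge_set(network, k + 1L))
  list(added = .keys_to_edges(setdiff(b, a)),
       removed = .keys_to_edges(setdiff(a, b)))
}
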