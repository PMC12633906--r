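#' Dynamic network over a fixed node set
#'
#' Per-time-point edge sets over the same nodes; edges are unordered pairs
#' `(i, j)`, `i < j`, with no self-loops.
#'
#' @param node_ids Character node identifiers (length p).
#' @param time_points Rescaled time points (length N).
#' @param edges List of N two-column integer matrices (`i < j`).
#' @param thetas Optional list of precision matrices (one per time point).
#' @param time_labels Optional raw time labels.
#' @param selection Optional list of `model_selection` objects per time.
#' @param params Named list of run parameters recorded in the manifest
#'   (e.g. `method`, `h`, `kernel`, `gamma`, `grid`, `m`, `seed`).
#' @return An object of class `dyn_net`.
#' @export
dynamic_network <- function(node_ids, time_points, edges, thetas = NULL,
                            time_labels = NULL, selection = NULL,
                            params = list()) {
  node_ids <- as.character(node_ids)
  p <- length(node_ids)
  if (length(edges) != length(time_points))
    .stop_arg("one edge set per time point required")
  edges <- lapply(edges, function(e) {
    e <- matrix(as.integer(e), ncol = 2L,
                dimnames = list(NULL, c("i", "j")))
    if (nrow(e) > 0L) {
      if (any(e < 1L) || any(e > p)) .stop_arg("edge references unknown node")
      if (any(e[, 1L] == e[, 2L])) .stop_arg("self-loops are not allowed")
      swap <- e[, 1L] > e[, 2L]
      e[swap, ] <- e[swap, 2:1]
      e <- unique(e[order(e[, 1L], e[, 2L]), , drop = FALSE])
    }
    e
  })
  structure(list(node_ids = node_ids,
                 time_points = time_points,
                 time_labels = if (is.null(time_labels)) time_points
                               else time_labels,
                 edges = edges,
                 thetas = thetas,
                 selection = selection,
                 params = params,
                 p = p, N = length(time_points)),
            class = "dyn_net")
}

#' @export
print.dyn_net <- function(x, ...) {
  m <- vapply(x$edges, nrow, 1L)
  cat(sprintf("Dynamic network: %d nodes, %d time points\n", x$p, x$N))
  cat(sprintf("  edges per time point: min %d, median %g, max %d\n",
              min(m), stats::median(m), max(m)))
  if (!is.null(x$params$method))
    cat(sprintf("  method: %s\n", x$params$method))
  invisible(x)
}

#' Edge set at one time point
#' @param network A `dyn_net`.
#' @param k Time index.
#' @return Two-column integer matrix (`i < j`).
#' @export
edge_set <- function(network, k) {
  stopifnot(inherits(network, "dyn_net"))
  if (k < 1L || k > network$N) .stop_arg("time index out of range")
  network$edges[[k]]
}

# canonical "i-j" keys for set operations on edge matrices
.edge_keys <- function(e) {
  if (nrow(e) == 0L) return(character(0))
  paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]), sep = "-")
}

.keys_to_edges <- function(keys) {
  if (length(keys) == 0L)
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  parts <- do.call(rbind, strsplit(keys, "-", fixed = TRUE))
  e <- matrix(as.integer(parts), ncol = 2L,
              dimnames = list(NULL, c("i", "j")))
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}
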