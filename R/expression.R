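#' Expression time series container
#'
#' Groups observations (samples x genes) by time point, with optional
#' biological replicates at each time point. Raw time labels are affinely
#' rescaled to \code{[0, 1]} via \code{(t - t_min) / (t_max - t_min)}; the
#' kernel bandwidth of [kernel_spec()] is interpreted on this rescaled axis.
#'
#' @param observations Either a numeric matrix (rows = samples, columns =
#'   genes) together with a `times` vector of length `nrow(observations)`,
#'   or a list of numeric matrices (one block of replicates per time point,
#'   each `n_k x p`) together with one time label per block.
#' @param times Numeric time labels (raw scale, e.g. hours); one per row of
#'   the matrix form or one per block of the list form.
#' @param gene_ids Character gene identifiers (length p). Defaults to column
#'   names or `g1..gp`.
#' @param center Logical; centre each gene to mean zero over all
#'   observations (the model assumes a zero mean vector). Default `TRUE`.
#'
#' @return An object of class `expr_ts` with fields `gene_ids`,
#'   `time_points` (rescaled, strictly increasing), `time_labels` (raw),
#'   `blocks` (list of `n_k x p` matrices), `n_k`, `N`, `p`, `centered`.
#' @export
expression_ts <- function(observations, times, gene_ids = NULL,
                          center = TRUE) {
  if (is.matrix(observations) || is.data.frame(observations)) {
    observations <- as.matrix(observations)
    if (!is.numeric(observations))
      .stop_arg("expression values must be numeric")
    if (length(times) != nrow(observations))
      .stop_arg("`times` must have one entry per sample (row)")
    if (is.null(gene_ids)) gene_ids <- colnames(observations)
    ord <- order(times)
    observations <- observations[ord, , drop = FALSE]
    times <- times[ord]
    uniq <- unique(times)
    blocks <- lapply(uniq, function(tt)
      observations[times == tt, , drop = FALSE])
    times <- uniq
  } else if (is.list(observations)) {
    blocks <- lapply(observations, as.matrix)
    if (length(times) != length(blocks))
      .stop_arg("`times` must have one entry per block")
    ord <- order(times)
    blocks <- blocks[ord]
    times <- times[ord]
    if (anyDuplicated(times))
      .stop_arg("time labels must be distinct in block form")
    if (is.null(gene_ids)) gene_ids <- colnames(blocks[[1L]])
  } else .stop_arg("`observations` must be a matrix or a list of matrices")

  p <- ncol(blocks[[1L]])
  if (p < 1L) .stop_arg("need at least one gene")
  if (any(vapply(blocks, ncol, 1L) != p))
    .stop_arg("all time-point blocks must have the same number of genes")
  if (any(vapply(blocks, function(b) anyNA(b) || !all(is.finite(b)), TRUE)))
    .stop_arg("expression values must be finite and non-missing")
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(p))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != p) .stop_arg("`gene_ids` must have length p")
  if (anyDuplicated(gene_ids)) .stop_arg("duplicate gene ids")

  if (!is.numeric(times) || anyNA(times))
    .stop_arg("time labels must be numeric and non-missing")
  N <- length(times)
  time_points <- if (N == 1L) 0 else (times - times[1L]) / (times[N] - times[1L])

  if (center) {
    mu <- colMeans(do.call(rbind, blocks))
    blocks <- lapply(blocks, function(b) sweep(b, 2L, mu))
  }
  blocks <- lapply(blocks, function(b) {
    colnames(b) <- gene_ids
    b
  })

  structure(list(gene_ids = gene_ids,
                 time_points = time_points,
                 time_labels = times,
                 blocks = blocks,
                 n_k = vapply(blocks, nrow, 1L),
                 N = N, p = p,
                 centered = isTRUE(center)),
            class = "expr_ts")
}

#' @export
print.expr_ts <- function(x, ...) {
  cat(sprintf("Expression time series: %d genes, %d time points, %d samples\n",
              x$p, x$N, sum(x$n_k)))
  cat(sprintf("  replicates per time point: %s\n",
              paste(unique(x$n_k), collapse = ", ")))
  cat(sprintf("  time labels: %s\n",
              paste(signif(x$time_labels, 4), collapse = ", ")))
  cat(sprintf("  centered: %s\n", x$centered))
  invisible(x)
}

# all observations stacked into one (sum n_k) x p matrix
.stack_obs <- function(data) do.call(rbind, data$blocks)
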