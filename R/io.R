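# Delimited-text input/output: expression matrices with per-sample time
# labels, per-time-point edge lists with a run manifest, optional GraphML.

.read_delim <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read an expression time series from a delimited file
#'
#' Expected layout (`orientation = "samples_by_genes"`): one row per sample,
#' a numeric time column (`time_column`), remaining columns one per gene.
#' With `orientation = "genes_by_samples"` the file has one row per gene
#' (first column the gene id) and one column per sample, and a
#' `time_table` file (columns `sample`, `time`) maps samples to times.
#' Tab-separated by default; `.csv` files are comma-separated.
#'
#' @param path Input file.
#' @param time_column Name of the time column. Default `"time"`.
#' @param orientation `"samples_by_genes"` (default) or
#'   `"genes_by_samples"`.
#' @param time_table Path to the sample-to-time table (genes-by-samples
#'   layout only).
#' @param center Centre genes, see [expression_ts()]. Default `TRUE`.
#' @return An [expression_ts()] object (times rescaled to `[0, 1]`; the raw
#'   labels are retained in `time_labels`).
#' @export
read_expression <- function(path, time_column = "time",
                            orientation = c("samples_by_genes",
                                            "genes_by_samples"),
                            time_table = NULL, center = TRUE) {
  orientation <- match.arg(orientation)
  df <- .read_delim(path)
  if (orientation == "samples_by_genes") {
    if (!time_column %in% names(df))
      .stop_arg(sprintf("time column '%s' not found in %s",
                        time_column, path))
    times <- df[[time_column]]
    mat <- df[, setdiff(names(df), time_column), drop = FALSE]
  } else {
    if (is.null(time_table))
      .stop_arg("`time_table` is required for genes-by-samples input")
    gene_ids <- df[[1L]]
    mat0 <- t(as.matrix(df[, -1L, drop = FALSE]))
    colnames(mat0) <- gene_ids
    tt <- .read_delim(time_table)
    if (!all(c("sample", "time") %in% names(tt)))
      .stop_arg("`time_table` must have columns 'sample' and 'time'")
    idx <- match(rownames(mat0), tt$sample)
    if (anyNA(idx))
      .stop_arg(sprintf("samples missing from the time table: %s",
                        paste(rownames(mat0)[is.na(idx)], collapse = ", ")))
    times <- tt$time[idx]
    mat <- as.data.frame(mat0)
  }
  for (j in seq_along(mat)) {
    col <- mat[[j]]
    if (!is.numeric(col) || anyNA(col)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(col))))[1L]
      .stop_arg(sprintf(
        "non-numeric or missing value in column '%s', row %d",
        names(mat)[j], bad))
    }
  }
  if (!is.numeric(times) || anyNA(times))
    .stop_arg("time labels must be numeric and non-missing")
  expression_ts(as.matrix(mat), times = times, gene_ids = colnames(mat),
                center = center)
}

#' Write an expression time series (samples-by-genes layout)
#'
#' Inverse of [read_expression()]: one row per observation with a leading
#' `time` column holding the raw time labels.
#'
#' @param data An [expression_ts()] object.
#' @param path Output file (`.csv` for comma-separated, else tabs).
#' @return `path`, invisibly.
#' @export
write_expression <- function(data, path) {
  stopifnot(inherits(data, "expr_ts"))
  X <- .stack_obs(data)
  df <- data.frame(time = rep(data$time_labels, data$n_k), X,
                   check.names = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count preprocessing recipe
#'
#' Filters genes to those with nonzero counts in at least
#' `min_nonzero_samples` samples and a mean count above `min_mean_count`;
#' applies `y = log2(x + 1)`; standardizes each surviving gene to mean 0
#' and standard deviation 1 over all samples; and keeps the
#' `top_variance_k` genes with the highest pre-standardization variance
#' (after standardization every variance is 1, so selection must use the
#' log-scale variance). Defaults follow a transcription-factor analysis of
#' 56 samples: 20 samples, 10 counts, 400 genes.
#'
#' @param counts Matrix of nonnegative counts, genes in rows (rownames are
#'   gene ids), samples in columns.
#' @param times Numeric time label per sample (column).
#' @param min_nonzero_samples,min_mean_count,top_variance_k Filtering
#'   thresholds; see above.
#' @return An [expression_ts()] object (already standardized; no further
#'   centering applied).
#' @export
preprocess_counts <- function(counts, times, min_nonzero_samples = 20L,
                              min_mean_count = 10, top_variance_k = 400L) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (length(times) != ncol(counts))
    .stop_arg("`times` must have one entry per sample (column)")
  keep <- rowSums(counts > 0) >= min_nonzero_samples &
          rowMeans(counts) > min_mean_count
  if (!any(keep)) .stop_arg("all genes removed by the count filters")
  y <- log2(counts[keep, , drop = FALSE] + 1)
  v <- apply(y, 1L, var)
  top <- utils::head(order(v, decreasing = TRUE), top_variance_k)
  y <- y[sort(top), , drop = FALSE]
  z <- t(scale(t(y)))                      # per-gene mean 0, sd 1
  expression_ts(t(z), times = times, gene_ids = rownames(z),
                center = FALSE)
}

#' Write a dynamic network as per-time-point edge lists with a manifest
#'
#' Each time point becomes `edges_<k>.tsv` with columns `node_i`, `node_j`
#' (`node_i < node_j` lexicographically) and `theta` (the precision entry;
#' `NA` when the network carries no precision matrices). A `manifest.tsv`
#' key-value file records the node ids, time labels/points and run
#' parameters so [read_networks()] can invert the write exactly.
#'
#' @param network A [dynamic_network()].
#' @param out_dir Output directory (created if missing).
#' @param graphml Also write `network_<k>.graphml` per time point.
#' @return `out_dir`, invisibly.
#' @export
write_networks <- function(network, out_dir, graphml = FALSE) {
  stopifnot(inherits(network, "dyn_net"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_len(network$N)) {
    e <- edge_set(network, k)
    ids <- network$node_ids
    a <- ids[e[, 1L]]; b <- ids[e[, 2L]]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    theta <- if (is.null(network$thetas)) rep(NA_real_, nrow(e)) else
      network$thetas[[k]][e]
    df <- data.frame(node_i = a, node_j = b, theta = theta,
                     stringsAsFactors = FALSE)
    df <- df[order(df$node_i, df$node_j), , drop = FALSE]
    utils::write.table(df, file.path(out_dir, sprintf("edges_%03d.tsv", k)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (graphml)
      .write_graphml(ids, e, file.path(out_dir,
                                       sprintf("network_%03d.graphml", k)))
  }
  man <- c(nodes = paste(network$node_ids, collapse = ","),
           time_labels = paste(network$time_labels, collapse = ","),
           time_points = paste(network$time_points, collapse = ","),
           vapply(network$params, function(v)
             paste(format(v, digits = 15, trim = TRUE), collapse = ","),
             ""))
  writeLines(paste(names(man), man, sep = "\t"),
             file.path(out_dir, "manifest.tsv"))
  invisible(out_dir)
}

.write_graphml <- function(ids, edges, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
               '  <graph edgedefault="undirected">'), con)
  writeLines(sprintf('    <node id="%s"/>', ids), con)
  if (nrow(edges) > 0L)
    writeLines(sprintf('    <edge source="%s" target="%s"/>',
                       ids[edges[, 1L]], ids[edges[, 2L]]), con)
  writeLines(c("  </graph>", "</graphml>"), con)
  invisible(path)
}

#' Read a dynamic network written by [write_networks()]
#'
#' @param dir Directory containing `edges_*.tsv` and `manifest.tsv`.
#' @return A [dynamic_network()]; the write -> read round trip is the
#'   identity for node ids, time labels and edge sets.
#' @export
read_networks <- function(dir) {
  man_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(man_path)) .stop_arg("no manifest.tsv in ", dir)
  man_lines <- strsplit(readLines(man_path), "\t", fixed = TRUE)
  man <- stats::setNames(
    vapply(man_lines, function(x) if (length(x) > 1L) x[2L] else "", ""),
    vapply(man_lines, `[[`, "", 1L))
  ids <- strsplit(man[["nodes"]], ",", fixed = TRUE)[[1L]]
  time_labels <- as.numeric(strsplit(man[["time_labels"]], ",")[[1L]])
  time_points <- as.numeric(strsplit(man[["time_points"]], ",")[[1L]])
  files <- sort(list.files(dir, pattern = "^edges_[0-9]+\\.tsv$",
                           full.names = TRUE))
  if (length(files) != length(time_points))
    .stop_arg("edge-list files do not match the manifest time points")
  edges <- lapply(files, function(f) {
    df <- utils::read.table(f, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    cbind(match(df$node_i, ids), match(df$node_j, ids))
  })
  params <- as.list(man[setdiff(names(man),
                                c("nodes", "time_labels", "time_points"))])
  dynamic_network(ids, time_points, edges, time_labels = time_labels,
                  params = params)
}

#' Write a metrics report as TSV plus a JSON summary
#'
#' @param report A `metrics_report` from [evaluate_networks()].
#' @param path Output TSV path; a `.json` summary of the time-averaged
#'   metrics is written next to it.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  means <- attr(report, "means")
  json <- paste0("{", paste(sprintf('"%s": %.10g', names(means), means),
                            collapse = ", "), "}")
  writeLines(json, sub("\\.[^.]*$", ".json", path))
  invisible(path)
}
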