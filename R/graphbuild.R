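# Correlation-graph construction over features. Vertices are features,
# edges connect pairs whose correlation across samples reaches a threshold
# t; edge weights store the correlation value itself so that downstream
# candidate filtering can recover the minimum internal correlation.

#' Transform counts before correlation
#'
#' @param counts samples x features numeric matrix.
#' @param transform one of `"identity"`, `"log2"`, `"log10"`.
#' @return matrix of the same shape.
#' @export
transform_counts <- function(counts,
                             transform = c("identity", "log2", "log10")) {
  transform <- match.arg(transform)
  if (transform == "identity") return(counts)
  if (any(counts <= 0))
    stop("log transform requires strictly positive counts; ",
         "apply filter_features(mode = 'nonzero') first")
  switch(transform, log2 = log2(counts), log10 = log10(counts))
}

#' Pairwise feature correlation matrix
#'
#' Computes the n x n matrix of pairwise correlations between feature
#' columns across samples. Spearman uses average ranks for ties. Features
#' with zero variance across samples cannot be placed in the correlation
#' graph; their rows/columns are set to `NA` with a warning and they are
#' skipped by [build_graph()].
#'
#' @param X samples x features numeric matrix (possibly transformed).
#' @param method `"pearson"` or `"spearman"`.
#' @return symmetric n x n correlation matrix with unit diagonal (diagonal
#'   is kept at 1 also for zero-variance features for bookkeeping).
#' @export
correlation_matrix <- function(X, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (nrow(X) < 3)
    warning("correlations estimated from fewer than 3 samples are unreliable")
  sds <- apply(X, 2, stats::sd)
  flat <- sds == 0
  if (any(flat))
    warning(sum(flat), " zero-variance feature(s) excluded from the ",
            "correlation graph: ",
            paste(utils::head(colnames(X)[flat], 5), collapse = ", "),
            if (sum(flat) > 5) ", ..." else "")
  corr <- suppressWarnings(stats::cor(X, method = method))
  corr[flat, ] <- NA_real_
  corr[, flat] <- NA_real_
  diag(corr) <- 1
  corr
}

#' Build the thresholded correlation graph
#'
#' Features are vertices; an undirected edge joins u and v iff
#' `corr(u, v) >= threshold` (positive correlation only). Edge weights carry
#' the correlation value. Isolated vertices are retained. Features whose
#' correlations are `NA` (zero variance) get no edges.
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @param feature_ids vertex names; defaults to `colnames(corr)`.
#' @param threshold correlation threshold t in (0, 1].
#' @return an [igraph::graph] with vertex attribute `name`, edge attribute
#'   `weight`, and graph attribute `threshold`.
#' @export
build_graph <- function(corr, feature_ids = colnames(corr), threshold = 0.9) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  n <- ncol(corr)
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(n))
  if (nrow(corr) != n) stop("corr must be square")
  if (max(abs(corr - t(corr)), na.rm = TRUE) > 1e-8)
    stop("corr must be symmetric")
  adj <- !is.na(corr) & corr >= threshold
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = feature_ids)
  if (nrow(idx) > 0) {
    g <- igraph::add_edges(g, t(idx), weight = corr[idx])
  }
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g
}

#' Export the edge list of a feature graph
#'
#' Writes a three-column TSV (two feature IDs and the correlation weight)
#' for external inspection of the graph.
#'
#' @param g graph from [build_graph()].
#' @param path output TSV path.
#' @export
write_edge_list <- function(g, path) {
  e <- igraph::as_data_frame(g, what = "edges")
  colnames(e) <- c("feature_a", "feature_b", "correlation")
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
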