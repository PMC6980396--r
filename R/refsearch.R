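# Reference-set discovery: enumerate candidate densely connected feature
# subsets (exact maximal cliques on small graphs, exemplar-based communities
# otherwise), filter by minimum internal correlation and size, score the
# survivors by the rank-1 residual of their raw count submatrix, and return
# the argmin.

new_candidate <- function(ids, corr) {
  ids <- sort(as.character(ids))
  min_cor <- if (length(ids) < 2) 1 else {
    sub <- corr[ids, ids]
    min(sub[upper.tri(sub)])
  }
  structure(list(feature_ids = ids,
                 size = length(ids),
                 min_internal_correlation = min_cor,
                 rank1_residual = NA_real_),
            class = "gbnorm_candidate")
}

#' Enumerate maximal cliques of a feature graph
#'
#' Exact enumeration of all maximal cliques (no returned vertex set is a
#' subset of another). Exponential in the worst case, hence guarded by a
#' vertex cap; larger graphs should use [detect_communities()].
#'
#' @param g graph from [build_graph()].
#' @param corr correlation matrix used to annotate each clique with its
#'   minimum internal correlation; defaults to reading edge weights.
#' @param vertex_cap refuse graphs with more vertices than this.
#' @return list of candidates, each with `feature_ids`, `size`,
#'   `min_internal_correlation`, `rank1_residual` (unset).
#' @export
maximal_cliques <- function(g, corr = NULL, vertex_cap = 500) {
  n <- igraph::vcount(g)
  if (n > vertex_cap)
    stop("graph has ", n, " vertices (cap ", vertex_cap, "); exact clique ",
         "enumeration is exponential - use detect_communities() instead")
  if (is.null(corr)) {
    corr <- matrix(1, n, n, dimnames = list(igraph::V(g)$name,
                                            igraph::V(g)$name))
    ends <- igraph::as_data_frame(g, what = "edges")
    if (nrow(ends) > 0) {
      corr[cbind(ends$from, ends$to)] <- ends$weight
      corr[cbind(ends$to, ends$from)] <- ends$weight
    }
  }
  cl <- igraph::max_cliques(g)
  lapply(cl, function(v) new_candidate(igraph::V(g)$name[as.integer(v)], corr))
}

# Frey-Dueck affinity propagation on a similarity matrix. Returns integer
# cluster labels (exemplar index per point) or NULL on non-convergence.
affinity_propagation <- function(S, preference = stats::median(S[upper.tri(S)]),
                                 damping = 0.9, maxit = 1000, convits = 50,
                                 seed = 1L) {
  n <- nrow(S)
  dimnames(S) <- NULL
  # nudge the preference infinitesimally downward so that exact ties
  # (uniform similarity blocks) resolve toward fewer exemplars instead of
  # an arbitrary jitter-driven split
  rng <- max(S[upper.tri(S)]) - min(S[upper.tri(S)])
  diag(S) <- preference - 1e-6 * rng - 1e-9 * (1 + abs(preference))
  # tiny deterministic jitter removes degenerate oscillations between
  # exactly tied solutions
  scale <- max(1e-9 * rng, 1e-12 * (1 + max(abs(S))))
  S <- S + with_seed(seed, matrix(stats::rnorm(n * n), n, n)) * scale
  R <- A <- matrix(0, n, n)
  e_hist <- matrix(FALSE, n, convits)
  converged <- FALSE
  it <- 0
  idx <- seq_len(n)
  while (it < maxit) {
    it <- it + 1
    # responsibilities
    AS <- A + S
    i1 <- max.col(AS, ties.method = "first")
    m1 <- AS[cbind(idx, i1)]
    AS[cbind(idx, i1)] <- -Inf
    m2 <- AS[cbind(idx, max.col(AS, ties.method = "first"))]
    Rnew <- S - m1
    Rnew[cbind(idx, i1)] <- S[cbind(idx, i1)] - m2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- rep(cs, each = n) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- (diag(A) + diag(R)) > 0
    e_hist[, (it - 1) %% convits + 1] <- ex
    if (it >= convits && any(ex)) {
      # stable iff every stored exemplar set equals the current one
      stable <- all(apply(e_hist, 2, identical, y = ex))
      if (stable) { converged <- TRUE; break }
    }
  }
  exemplars <- which((diag(A) + diag(R)) > 0)
  if (!converged || length(exemplars) == 0) return(NULL)
  labels <- exemplars[max.col(S[, exemplars, drop = FALSE],
                              ties.method = "first")]
  labels[exemplars] <- exemplars
  labels
}

#' Partition features into candidate communities
#'
#' Clusters the features of a similarity (correlation) matrix into
#' non-overlapping groups by affinity propagation, the exemplar-based
#' message-passing algorithm that consumes a similarity matrix directly and
#' needs no preset cluster count. Each group becomes one candidate. If the
#' message passing does not converge, the function falls back to the
#' deterministic partition into connected components of the graph
#' thresholded at `threshold`, with a warning.
#'
#' @param corr symmetric similarity (correlation) matrix; `NA`
#'   rows/columns (zero-variance features) become singleton candidates.
#' @param feature_ids vertex names; defaults to `colnames(corr)`.
#' @param threshold threshold used only by the connected-components
#'   fallback.
#' @param preference exemplar preference (diagonal of the similarity);
#'   default median off-diagonal similarity.
#' @param damping message damping factor in `[0.5, 1)`.
#' @param maxit,convits iteration cap and required stable iterations.
#' @param seed seed for the deterministic degeneracy-breaking jitter.
#' @return list of candidates as in [maximal_cliques()].
#' @export
detect_communities <- function(corr, feature_ids = colnames(corr),
                               threshold = 0.9, preference = NULL,
                               damping = 0.9, maxit = 1000, convits = 50,
                               seed = 1L) {
  n <- ncol(corr)
  if (n < 2) stop("community detection needs at least 2 features")
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(n))
  dimnames(corr) <- list(feature_ids, feature_ids)
  usable <- !apply(is.na(corr) & row(corr) != col(corr), 2, all)
  S <- corr[usable, usable, drop = FALSE]
  S[is.na(S)] <- -1  # undefined correlations: maximally dissimilar
  if (is.null(preference)) preference <- stats::median(S[upper.tri(S)])
  labels <- if (sum(usable) >= 2) {
    affinity_propagation(S, preference = preference, damping = damping,
                         maxit = maxit, convits = convits, seed = seed)
  } else NULL
  if (is.null(labels) && sum(usable) >= 2) {
    warning("affinity propagation did not converge; falling back to ",
            "connected components at threshold ", threshold)
    g <- build_graph(corr[usable, usable, drop = FALSE], threshold = threshold)
    labels <- igraph::components(g)$membership
  }
  groups <- split(rownames(S), labels)
  extra <- feature_ids[!usable]
  cands <- c(lapply(groups, new_candidate, corr = corr),
             lapply(extra, new_candidate, corr = corr))
  names(cands) <- NULL
  cands
}

#' Rank-1 residual of a count submatrix
#'
#' For singular values `s_1 >= ... >= s_d` of the candidate's read-count
#' submatrix, returns `sum(s_i^2, i >= 2) / sum(s_i^2)`: the fraction of
#' squared spectral mass outside the best rank-1 approximation. Zero iff
#' the matrix has rank <= 1, as expected for the raw counts of true
#' reference features; strictly larger for sets mixing unequal fold-change
#' profiles.
#'
#' @param C_R numeric matrix (samples x candidate features).
#' @return a real in `[0, 1)`.
#' @export
rank1_residuals <- function(C_R) {
  C_R <- as.matrix(C_R)
  if (all(C_R == 0)) stop("rank-1 residual is undefined for an all-zero matrix")
  s2 <- svd(C_R, nu = 0, nv = 0)$d^2
  sum(s2[-1]) / sum(s2)
}

score_candidates <- function(candidates, counts) {
  for (i in seq_along(candidates)) {
    candidates[[i]]$rank1_residual <-
      rank1_residuals(counts[, candidates[[i]]$feature_ids, drop = FALSE])
  }
  candidates
}

#' Identify the reference feature set
#'
#' The core discovery pipeline: transform the (already feature-filtered)
#' counts, compute pairwise feature correlations, enumerate candidate
#' subsets (exact maximal cliques when the graph is small and
#' `mode = "exact"`, affinity-propagation communities otherwise), drop
#' candidates whose minimum internal correlation falls below `threshold` or
#' whose size falls below `min_size`, score the survivors by
#' [rank1_residuals()] on their raw count submatrix, and return the argmin.
#' Ties are broken by larger size, then by the lexicographically smallest
#' feature-ID set.
#'
#' @param counts samples x features count matrix, feature-filtered so that
#'   log transforms are defined (see [filter_features()]).
#' @param transform,correlation,threshold graph construction parameters;
#'   defaults log2 + Pearson, t = 0.9.
#' @param min_size smallest candidate size eligible for selection.
#' @param mode `"community"` (default, scales to large graphs) or
#'   `"exact"` (maximal cliques; errors above `clique_cap` vertices).
#' @param clique_cap vertex cap for exact mode.
#' @param seed seed forwarded to [detect_communities()].
#' @param ap_control optional list of overrides for the community step
#'   (`preference`, `damping`, `maxit`, `convits`).
#' @return an object of class `reference_set`: list with `feature_ids`,
#'   `score` (winning rank-1 residual), `provenance` (`"clique"` or
#'   `"community"`), `candidate` (the winning candidate), and `n_candidates`.
#' @export
identify_references <- function(counts,
                                transform = c("log2", "identity", "log10"),
                                correlation = c("pearson", "spearman"),
                                threshold = 0.9, min_size = 10,
                                mode = c("community", "exact"),
                                clique_cap = 500, seed = 1L,
                                ap_control = list()) {
  transform <- match.arg(transform)
  correlation <- match.arg(correlation)
  mode <- match.arg(mode)
  validate_counts(counts)
  if (nrow(counts) < 3)
    stop("reference identification needs at least 3 samples")
  X <- transform_counts(counts, transform)
  corr <- correlation_matrix(X, correlation)
  if (mode == "exact") {
    g <- build_graph(corr, threshold = threshold)
    candidates <- maximal_cliques(g, corr = corr, vertex_cap = clique_cap)
    provenance <- "clique"
  } else {
    ap <- utils::modifyList(list(preference = NULL, damping = 0.9,
                                 maxit = 1000, convits = 50), ap_control)
    candidates <- detect_communities(corr, threshold = threshold,
                                     preference = ap$preference,
                                     damping = ap$damping, maxit = ap$maxit,
                                     convits = ap$convits, seed = seed)
    provenance <- "community"
  }
  keep <- vapply(candidates, function(cd) {
    cd$size >= min_size && cd$min_internal_correlation >= threshold
  }, logical(1))
  survivors <- candidates[keep]
  if (length(survivors) == 0)
    stop("no reference community found: no candidate of size >= ", min_size,
         " with minimum internal correlation >= ", threshold,
         "; consider lowering threshold or min_size")
  survivors <- score_candidates(survivors, counts)
  res <- vapply(survivors, `[[`, numeric(1), "rank1_residual")
  sizes <- vapply(survivors, `[[`, numeric(1), "size")
  keys <- vapply(survivors, function(cd) paste(cd$feature_ids, collapse = "\r"),
                 character(1))
  # residuals within numerical noise of the minimum count as ties, broken
  # by larger size, then by lexicographically smallest feature-ID set
  tied <- which(res <= min(res) + 1e-12)
  ord <- tied[order(-sizes[tied], keys[tied])]
  best <- survivors[[ord[1]]]
  structure(list(feature_ids = best$feature_ids,
                 score = best$rank1_residual,
                 provenance = provenance,
                 candidate = best,
                 n_candidates = length(candidates),
                 config = list(transform = transform,
                               correlation = correlation,
                               threshold = threshold, min_size = min_size,
                               mode = mode, seed = seed)),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("Reference set (", x$provenance, "): ", length(x$feature_ids),
      " features\n", sep = "")
  cat("  rank-1 residual: ", format(x$score, digits = 4),
      " | min internal correlation: ",
      format(x$candidate$min_internal_correlation, digits = 4), "\n", sep = "")
  cat("  config: ", x$config$transform, " + ", x$config$correlation,
      ", t = ", x$config$threshold, ", min_size = ", x$config$min_size,
      "\n", sep = "")
  invisible(x)
}
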