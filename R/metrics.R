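# Evaluation of reference identification and normalization quality against
# a known ground truth: precision of the identified feature set, and the
# condition-number based deviation (cdev) of a normalized matrix from the
# ground-truth normalization.

#' Precision of reference identification
#'
#' Fraction of the identified features that are true references:
#' `|identified intersect truth| / |identified|`.
#'
#' @param identified character vector (or `reference_set`) of identified
#'   feature IDs; must be non-empty.
#' @param truth character vector of true reference feature IDs.
#' @return a real in `[0, 1]`.
#' @export
precision_score <- function(identified, truth) {
  if (inherits(identified, "reference_set")) identified <- identified$feature_ids
  identified <- unique(as.character(identified))
  if (length(identified) == 0) stop("identified set is empty")
  truth <- unique(as.character(truth))
  length(intersect(identified, truth)) / length(identified)
}

# Reduced least-squares data shared by transform_matrix() and cdev():
# SVD of A_X, numerical rank r, and the r x n matrix T = D_r^{-1} U_r' A,
# so that the minimum-norm solution is B = V_r T and the non-zero singular
# values of B are exactly those of T.
lstsq_reduced <- function(A_X, A, rank_tol = 1e-12) {
  if (!all(dim(A_X) == dim(A)))
    stop("A_X and A must have identical shape")
  sv <- svd(A_X)
  tol <- max(dim(A_X)) * sv$d[1] * rank_tol
  r <- sum(sv$d > tol)
  if (r == 0) stop("A_X has numerical rank 0")
  Tm <- (t(sv$u[, seq_len(r), drop = FALSE]) %*% A) / sv$d[seq_len(r)]
  list(V = sv$v[, seq_len(r), drop = FALSE], T = Tm, rank = r)
}

#' Least-squares transform between two normalizations
#'
#' The matrix `B_X` solving `A_X %*% B_X ~ A` in the least-squares sense:
#' the normal-equations solution `(A_X' A_X)^{-1} (A_X' A)` when `A_X` has
#' full column rank, and the minimum-norm SVD solution otherwise (always the
#' case when there are fewer samples than features). Singular values of
#' `A_X` below `max(dim) * sigma_1 * 1e-12` are treated as zero.
#'
#' @param A_X candidate normalized matrix (samples x features).
#' @param A ground-truth normalized matrix, same shape and ordering.
#' @return n x n matrix `B_X`.
#' @export
transform_matrix <- function(A_X, A) {
  red <- lstsq_reduced(A_X, A)
  red$V %*% red$T
}

#' Condition-number based deviation from a ground-truth normalization
#'
#' `cdev(A_X, A)` is the spectral condition number of the least-squares
#' transform `B_X` taking `A_X` to `A`: the ratio of the largest to the
#' r-th largest singular value of `B_X`, where r is the numerical rank of
#' `A_X`. It equals 1 exactly when `B_X` acts as a scalar multiple of the
#' identity on the resolvable subspace - i.e. when `A_X` is a valid
#' normalization (any positive multiple of `A`) - and grows as the
#' per-sample scaling distorts the ground truth. Scale-invariant in both
#' arguments.
#'
#' With very many features the SVD cost can be bounded by evaluating cdev
#' on a seeded random subset of feature columns (`max_features`); the
#' subset used is recorded in the result's attributes.
#'
#' @param A_X candidate normalized matrix (samples x features).
#' @param A ground-truth normalized matrix, same shape and ordering.
#' @param max_features optional cap on the number of feature columns used.
#' @param seed seed for the column subsample when the cap binds.
#' @return a real `>= 1` (possibly `Inf` when `A` is invisible to `A_X`'s
#'   row space in some resolvable direction).
#' @export
cdev <- function(A_X, A, max_features = 2000, seed = 1L) {
  if (!all(dim(A_X) == dim(A)))
    stop("A_X and A must have identical shape")
  subset_used <- NULL
  if (!is.null(max_features) && ncol(A_X) > max_features) {
    subset_used <- with_seed(seed, sort(sample.int(ncol(A_X), max_features)))
    A_X <- A_X[, subset_used, drop = FALSE]
    A <- A[, subset_used, drop = FALSE]
  }
  red <- lstsq_reduced(A_X, A)
  s <- svd(red$T, nu = 0, nv = 0)$d
  out <- s[1] / s[red$rank]
  if (!is.null(subset_used))
    attr(out, "feature_subset") <- list(max_features = max_features,
                                        seed = seed, columns = subset_used)
  out
}

#' Evaluate identification and/or normalization against ground truth
#'
#' @param identified identified reference IDs (optional).
#' @param truth true reference IDs (optional).
#' @param A_X,A candidate and ground-truth normalized matrices (optional).
#' @param ... passed to [cdev()].
#' @return list with `precision`, `cdev`, `n_identified`, `n_truth` (`NA`
#'   where the corresponding inputs were not given).
#' @export
evaluate_normalization <- function(identified = NULL, truth = NULL,
                                   A_X = NULL, A = NULL, ...) {
  res <- list(precision = NA_real_, cdev = NA_real_,
              n_identified = NA_integer_, n_truth = NA_integer_)
  if (!is.null(identified) && !is.null(truth)) {
    if (inherits(identified, "reference_set"))
      identified <- identified$feature_ids
    res$precision <- precision_score(identified, truth)
    res$n_identified <- length(unique(identified))
    res$n_truth <- length(unique(truth))
  }
  if (!is.null(A_X) && !is.null(A)) res$cdev <- as.numeric(cdev(A_X, A, ...))
  res
}
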