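# Per-sample scaling factors and normalized matrices. The reference-based
# factor of sample i is the sum of the reference features' read counts in
# that sample; dividing each row by its factor yields a manifest abundance
# matrix equal to the true abundance up to one global constant when the
# references are genuine (and only then).

new_scaling_factors <- function(values, method, reference_ids = NULL) {
  if (any(values <= 0))
    stop("degenerate sample: non-positive ", method, " scaling factor for ",
         paste(names(values)[values <= 0], collapse = ", "))
  structure(list(values = values,
                 relative = values / geometric_mean(values),
                 method = method,
                 reference_ids = reference_ids),
            class = "scaling_factors")
}

#' @export
print.scaling_factors <- function(x, ...) {
  cat("Scaling factors (", x$method, ") for ", length(x$values),
      " samples\n", sep = "")
  print(utils::head(x$values))
  invisible(x)
}

#' Reference-based scaling factors
#'
#' `values[i] = sum_{j in R} c_ij`, the read-count sum of the reference
#' features in sample i.
#'
#' @param counts samples x features count matrix.
#' @param references a `reference_set` from [identify_references()] or a
#'   character vector of feature IDs.
#' @return a `scaling_factors` object with fields `values` (raw scale),
#'   `relative` (rescaled to geometric mean 1), `method`, `reference_ids`.
#' @export
reference_scale_factors <- function(counts, references) {
  validate_counts(counts)
  ids <- if (inherits(references, "reference_set")) references$feature_ids
         else as.character(references)
  if (length(ids) == 0) stop("reference set is empty")
  missing_ids <- setdiff(ids, colnames(counts))
  if (length(missing_ids) > 0)
    stop("reference feature(s) absent from the count matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "),
         if (length(missing_ids) > 5) ", ..." else "")
  values <- rowSums(counts[, ids, drop = FALSE])
  new_scaling_factors(values, "gbnorm", reference_ids = ids)
}

#' Normalize counts by per-sample factors
#'
#' `a*_ij = c_ij / N_i`.
#'
#' @param counts samples x features count matrix.
#' @param factors a `scaling_factors` object or a positive numeric vector of
#'   length `nrow(counts)`.
#' @return normalized matrix of the same shape and dimnames.
#' @export
normalize_counts <- function(counts, factors) {
  validate_counts(counts)
  values <- if (inherits(factors, "scaling_factors")) factors$values
            else factors
  if (length(values) != nrow(counts))
    stop("factor vector length (", length(values),
         ") does not match the number of samples (", nrow(counts), ")")
  if (any(values <= 0)) stop("scaling factors must be strictly positive")
  counts / values
}

#' One-call graph-based normalization
#'
#' Runs the two-stage procedure: identify references on `counts` (or on
#' `identify_on` when the references should be discovered on a different,
#' e.g. larger, matrix), then scale `counts` by the reference read-count
#' sums.
#'
#' @param counts samples x features count matrix to normalize.
#' @param identify_on matrix used for reference discovery; default `counts`.
#' @param filter,quantile detection filter applied before discovery (see
#'   [filter_features()]).
#' @param ... passed to [identify_references()].
#' @return list with `normalized`, `factors`, `references`.
#' @export
gbnorm <- function(counts, identify_on = counts, filter = "nonzero",
                   quantile = 0.25, ...) {
  flt <- filter_features(identify_on, mode = filter, quantile = quantile)
  refs <- identify_references(flt$counts, ...)
  factors <- reference_scale_factors(counts, refs)
  list(normalized = normalize_counts(counts, factors),
       factors = factors,
       references = refs)
}

#' Baseline global scaling factors
#'
#' Classical between-sample scaling methods, implemented from their original
#' definitions, for comparison against the reference-based factors:
#'
#' * `tc` - total count: `N_i = M_i`.
#' * `uq` - upper quartile: 75th percentile of each sample's non-zero
#'   counts, rescaled so the factors' geometric mean equals that of the
#'   library sizes.
#' * `rle` - relative log expression (median-of-ratios): per sample the
#'   median over all-positive features of `c_ij / geomean_i'(c_i'j)`.
#' * `tmm` - trimmed mean of M-values: weighted mean of per-feature
#'   log-ratios against a reference sample after trimming 30% of the
#'   log-ratios and 5% of the absolute intensities, with inverse-variance
#'   weights; the reference sample is the one whose upper-quartile statistic
#'   is closest to the mean. Returned as factor x library size (effective
#'   library size).
#' * `poissonseq` - iterative Poisson goodness-of-fit: starting from total
#'   counts, score each feature's fit to the common-proportion null, keep
#'   the features inside the central goodness-of-fit quantile window, and
#'   re-estimate depths from the kept features until convergence.
#'
#' @param counts samples x features count matrix.
#' @param method one of `"tc"`, `"uq"`, `"tmm"`, `"rle"`, `"poissonseq"`.
#' @param uq_p quantile used by `uq` (default 0.75).
#' @param tmm_logratio_trim,tmm_sum_trim TMM trim fractions.
#' @param ps_window central quantile window kept by `poissonseq`.
#' @param ps_tol,ps_maxit PoissonSeq convergence tolerance (relative change)
#'   and iteration cap.
#' @return a `scaling_factors` object; `relative` holds the geometric-mean-1
#'   copy used for cross-method comparison.
#' @export
baseline_factors <- function(counts,
                             method = c("tc", "uq", "tmm", "rle", "poissonseq"),
                             uq_p = 0.75, tmm_logratio_trim = 0.3,
                             tmm_sum_trim = 0.05, ps_window = c(0.25, 0.75),
                             ps_tol = 1e-8, ps_maxit = 20) {
  method <- match.arg(method)
  validate_counts(counts)
  M <- rowSums(counts)
  values <- switch(method,
    tc = M,
    uq = {
      q <- apply(counts, 1, function(x) {
        nz <- x[x > 0]
        if (length(nz) == 0) stop("uq: a sample has no non-zero counts")
        stats::quantile(nz, uq_p, names = FALSE, type = 7)
      })
      q * geometric_mean(M) / geometric_mean(q)
    },
    rle = {
      pos <- apply(counts > 0, 2, all)
      if (!any(pos))
        stop("rle: no feature has positive counts in every sample")
      lgm <- colMeans(log(counts[, pos, drop = FALSE]))
      apply(exp(log(counts[, pos, drop = FALSE]) -
                rep(lgm, each = nrow(counts))), 1, stats::median)
    },
    tmm = tmm_factors(counts, M, tmm_logratio_trim, tmm_sum_trim) * M,
    poissonseq = poissonseq_factors(counts, ps_window, ps_tol, ps_maxit))
  new_scaling_factors(values, method)
}

# TMM per Robinson & Oshlack: pairwise weighted trimmed mean of log ratios
# against a reference sample. Returns the unit-mean-free factor f_i (not yet
# multiplied by library size).
tmm_factors <- function(counts, M, logratio_trim, sum_trim) {
  m <- nrow(counts)
  f75 <- apply(counts, 1, stats::quantile, probs = 0.75, names = FALSE) / M
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(m), function(i) {
    if (i == ref) return(1)
    obs <- counts[i, ]; rf <- counts[ref, ]
    nO <- M[i]; nR <- M[ref]
    logR <- log2((obs / nO) / (rf / nR))
    absE <- (log2(obs / nO) + log2(rf / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - rf) / nR / rf
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (length(logR) == 0 || max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * sum_trim) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
            rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep] / v[keep], na.rm = TRUE) /
       sum(1 / v[keep], na.rm = TRUE))
  }, numeric(1))
  names(f) <- rownames(counts)
  f
}

# Iterative Poisson goodness-of-fit depth estimation (Li et al.): the
# per-feature chi-square statistic against expected counts d_i * total_j
# selects a central window of putatively non-differential features, from
# which depths are re-estimated.
poissonseq_factors <- function(counts, window, tol, maxit) {
  m <- nrow(counts)
  total_j <- colSums(counts)
  use <- total_j > 0
  if (!any(use)) stop("poissonseq: empty count matrix")
  cnt <- counts[, use, drop = FALSE]
  total_j <- total_j[use]
  d <- rowSums(cnt) / sum(cnt)
  kept <- NULL
  for (it in seq_len(maxit)) {
    expected <- outer(d, total_j)
    gof <- colSums((cnt - expected)^2 / expected)
    qs <- stats::quantile(gof, window, names = FALSE, type = 7)
    kept <- gof >= qs[1] & gof <= qs[2]
    if (!any(kept)) stop("poissonseq: no feature retained in the quantile window")
    d_new <- rowSums(cnt[, kept, drop = FALSE]) / sum(cnt[, kept, drop = FALSE])
    delta <- max(abs(d_new - d) / d)
    d <- d_new
    if (delta < tol) break
  }
  values <- rowSums(cnt[, kept, drop = FALSE])
  names(values) <- rownames(counts)
  values
}
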