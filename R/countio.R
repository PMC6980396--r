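#' @keywords internal
"_PACKAGE"

# Canonical in-memory representation of a count matrix: a base numeric matrix
# with samples in rows and features in columns, both fully named with unique
# identifiers. All functions in the package consume and produce this layout.

#' Validate a count matrix
#'
#' Checks that `counts` is a numeric matrix in the canonical samples x
#' features orientation with unique row (sample) and column (feature) names
#' and no negative entries. Real-valued (expected) counts, e.g. RSEM output,
#' are accepted; integrality is not enforced.
#'
#' @param counts numeric matrix, samples in rows, features in columns.
#' @return `counts`, invisibly, after validation.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix (samples x features)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample (row) and feature (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate feature identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (anyNA(counts))
    stop("counts contain missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at sample '%s', feature '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  invisible(counts)
}

#' Read a count matrix from delimited text
#'
#' Reads a TSV/CSV count table with one header line and one leading
#' identifier column, and returns the matrix in the canonical samples x
#' features orientation (transposing if the file stores features in rows,
#' the common count-table layout and the default).
#'
#' @param path path to a delimited text file.
#' @param orientation `"features_in_rows"` (default; header = sample IDs,
#'   first column = feature IDs) or `"samples_in_rows"`.
#' @param delimiter field separator, default tab.
#' @return numeric matrix, samples x features.
#' @export
read_counts <- function(path,
                        orientation = c("features_in_rows", "samples_in_rows"),
                        delimiter = "\t") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("expected an identifier column plus data columns in ", path)
  ids <- df[[1]]
  body <- df[, -1, drop = FALSE]
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1) num <- matrix(num, nrow = 1)
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("malformed numeric cell at row '%s', column '%s' in %s",
                 ids[bad[1]], colnames(body)[bad[2]], path))
  }
  dimnames(num) <- list(ids, colnames(body))
  counts <- if (orientation == "features_in_rows") t(num) else num
  validate_counts(counts)
  counts
}

#' Write a count or normalized matrix to delimited text
#'
#' Integer-valued matrices round-trip bit-compatibly through [read_counts()];
#' real-valued matrices are written with 15 significant digits.
#'
#' @param M numeric matrix, samples x features (canonical orientation).
#' @param path output file path.
#' @param orientation layout on disk, as in [read_counts()].
#' @param delimiter field separator, default tab.
#' @param id_header name of the leading identifier column.
#' @export
write_counts <- function(M, path,
                         orientation = c("features_in_rows", "samples_in_rows"),
                         delimiter = "\t", id_header = "feature_id") {
  orientation <- match.arg(orientation)
  out <- if (orientation == "features_in_rows") t(M) else M
  if (orientation == "samples_in_rows" && missing(id_header))
    id_header <- "sample_id"
  integral <- all(out == round(out)) && max(abs(out)) < 2^53
  cells <- if (integral) {
    format(out, scientific = FALSE, trim = TRUE)
  } else {
    format(out, digits = 15, scientific = TRUE, trim = TRUE)
  }
  df <- data.frame(rownames(out), cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_header, colnames(out))
  ok <- tryCatch({
    suppressWarnings(utils::write.table(df, path, sep = delimiter,
                                        quote = FALSE, row.names = FALSE,
                                        col.names = TRUE))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Library sizes
#'
#' Total read count per sample, `M_i = sum_j c_ij`.
#'
#' @param counts samples x features count matrix.
#' @return named numeric vector of length `nrow(counts)`.
#' @export
library_sizes <- function(counts) {
  validate_counts(counts)
  rowSums(counts)
}

#' Filter features by detection level
#'
#' Reduces the feature set to those reliably detected in every sample, the
#' standard pruning step before correlation-graph construction.
#'
#' * `mode = "nonzero"` keeps feature j iff `c_ij > 0` in every sample i.
#' * `mode = "quantile"` keeps feature j iff in every sample its count
#'   strictly exceeds that sample's `quantile` level of the sample's
#'   non-zero counts (lower quartile by default). Quantiles use linear
#'   interpolation between order statistics (type 7) so the kept set is
#'   reproducible.
#'
#' @param counts samples x features count matrix.
#' @param mode one of `"none"`, `"nonzero"`, `"quantile"`.
#' @param quantile quantile level in `[0, 1)`, used only in quantile mode.
#' @return list with `counts` (filtered matrix, feature order preserved) and
#'   `kept` (integer indices into the original columns).
#' @export
filter_features <- function(counts, mode = c("nonzero", "none", "quantile"),
                            quantile = 0.25) {
  mode <- match.arg(mode)
  validate_counts(counts)
  keep <- switch(mode,
    none = rep(TRUE, ncol(counts)),
    nonzero = apply(counts > 0, 2, all),
    quantile = {
      if (quantile < 0 || quantile >= 1) stop("quantile must be in [0, 1)")
      cut <- apply(counts, 1, function(x) {
        nz <- x[x > 0]
        if (length(nz) == 0) Inf else stats::quantile(nz, quantile,
                                                      names = FALSE, type = 7)
      })
      apply(counts > cut, 2, all)  # counts > cut recycles cut down columns
    })
  if (!any(keep))
    stop("all features removed by the '", mode,
         "' filter; relax the filter or check the input matrix")
  list(counts = counts[, keep, drop = FALSE], kept = unname(which(keep)))
}
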