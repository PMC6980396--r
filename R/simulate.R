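# Synthetic validation sets with known ground truth, emulating the
# structure of spike-in validation experiments: a block of features whose
# expected abundance is constant across all samples (the references), plus
# co-expressed differential "pathway" groups whose abundance follows a
# shared per-condition fold-change profile. Wide expression ranges, widely
# varying library sizes and count noise make the recovery problem realistic
# while precision and cdev remain exactly computable.

#' Simulate a validation count matrix with known references
#'
#' Generation model, fully reproducible from `seed`:
#'
#' 1. Samples are partitioned near-evenly into `n_conditions` conditions.
#' 2. Baseline expected abundances are drawn log-uniformly:
#'    references from `ref_abundance_range` (kept high enough that their
#'    expected counts are reliably detected), differential features from
#'    `abundance_range` (wide dynamic range).
#' 3. `n_templates` pathway templates are created, each with a size (drawn
#'    log-normally around 90 genes unless `pathway_sizes` is given) and a
#'    per-condition log2 fold-change profile drawn `N(0, fold_change_sd)`;
#'    `n_pathways` templates are sampled to build the set. All features of
#'    a group share the group profile; each feature additionally receives
#'    its own per-condition log2 deviation `N(0, within_group_sd)`,
#'    constant across replicates, so that co-expression within a group is
#'    strong but not exactly proportional (as for real co-regulated genes).
#'    Reference features have constant abundance across all samples.
#' 4. Library sizes are drawn log-normally with mean `library_size_mean`
#'    and coefficient of variation `library_size_cv`.
#' 5. Expected counts are `M_i * b_ij` where `b_ij` is the per-sample
#'    relative abundance, optionally length-weighted by `length_factors`.
#' 6. Counts are the expectations themselves (`noise = "none"`, real-valued
#'    so algebraic identities are exact), Poisson draws, or negative
#'    binomial draws with dispersion `nb_dispersion`.
#'
#' @param m_samples number of samples.
#' @param n_conditions number of conditions the samples are split into.
#' @param n_refs number of reference features.
#' @param pathway_sizes optional integer vector of differential group
#'   sizes; overrides the template draw.
#' @param n_pathways,n_templates number of groups per set and size of the
#'   template pool they are drawn from.
#' @param fold_change_sd sd of per-condition group log2 fold changes.
#' @param within_group_sd sd of per-feature, per-condition log2 deviations
#'   from the group profile; 0 makes within-group co-expression exactly
#'   proportional.
#' @param abundance_range,ref_abundance_range `(low, high)` of the
#'   log-uniform baseline abundance draws.
#' @param library_size_mean,library_size_cv mean and CV of library sizes.
#' @param noise `"poisson"` (default), `"none"`, or `"nb"`.
#' @param nb_dispersion negative binomial dispersion (`size = 1/dispersion`).
#' @param length_factors optional per-feature positive length weights,
#'   length `n_refs + sum(pathway sizes)`.
#' @param seed integer seed.
#' @return list with `counts` (samples x features matrix) and `truth`, a
#'   `simulation_truth` object: `abundance` (expected abundance `a_ij`),
#'   `relative_abundance` (rows sum to 1), `reference_ids`,
#'   `reference_indices`, `pathway_assignment`, `library_sizes`,
#'   `condition`, and the realized `config`.
#' @export
simulate_validation_set <- function(m_samples = 41, n_conditions = 13,
                                    n_refs = 60, pathway_sizes = NULL,
                                    n_pathways = 8, n_templates = 16,
                                    fold_change_sd = 1.5,
                                    within_group_sd = 0.1,
                                    abundance_range = c(0.5, 5000),
                                    ref_abundance_range = c(400, 20000),
                                    library_size_mean = 3e6,
                                    library_size_cv = 0.7,
                                    noise = c("poisson", "none", "nb"),
                                    nb_dispersion = 0.05,
                                    length_factors = NULL, seed = 1L) {
  noise <- match.arg(noise)
  if (n_refs < 1) stop("n_refs must be >= 1")
  if (m_samples < n_conditions)
    stop("m_samples must be >= n_conditions")
  stopifnot(fold_change_sd > 0, within_group_sd >= 0,
            all(abundance_range > 0), all(ref_abundance_range > 0),
            library_size_mean > 0, library_size_cv > 0, nb_dispersion > 0)
  with_seed(seed, {
    # pathway pool
    if (is.null(pathway_sizes)) {
      template_sizes <- pmin(pmax(round(exp(stats::rnorm(
        n_templates, log(90), 0.35))), 30), 200)
      chosen <- sort(sample.int(n_templates, n_pathways))
      pathway_sizes <- template_sizes[chosen]
      template_ids <- chosen
    } else {
      pathway_sizes <- as.integer(pathway_sizes)
      template_ids <- seq_along(pathway_sizes)
    }
    if (length(pathway_sizes) == 0) stop("pathway list must be non-empty")
    n_diff <- sum(pathway_sizes)
    n <- n_refs + n_diff
    condition <- sort(rep_len(seq_len(n_conditions), m_samples))

    ref_ids <- sprintf("ref_%03d", seq_len(n_refs))
    pw_lab <- sprintf("pw%02d", template_ids)
    diff_ids <- unlist(lapply(seq_along(pathway_sizes), function(g)
      sprintf("%s_%03d", pw_lab[g], seq_len(pathway_sizes[g]))))
    feature_ids <- c(ref_ids, diff_ids)
    sample_ids <- sprintf("s%02d", seq_len(m_samples))
    group <- c(rep("reference", n_refs), rep(pw_lab, pathway_sizes))

    base <- c(exp(stats::runif(n_refs, log(ref_abundance_range[1]),
                               log(ref_abundance_range[2]))),
              exp(stats::runif(n_diff, log(abundance_range[1]),
                               log(abundance_range[2]))))

    # per-condition log2 fold changes: group profile + per-feature jitter
    lfc <- matrix(0, n_conditions, n)
    off <- n_refs
    for (g in seq_along(pathway_sizes)) {
      profile <- stats::rnorm(n_conditions, 0, fold_change_sd)
      cols <- off + seq_len(pathway_sizes[g])
      lfc[, cols] <- profile +
        matrix(stats::rnorm(n_conditions * pathway_sizes[g], 0,
                            within_group_sd),
               n_conditions, pathway_sizes[g])
      off <- off + pathway_sizes[g]
    }
    abundance <- rep(base, each = m_samples) * 2^lfc[condition, , drop = FALSE]
    dimnames(abundance) <- list(sample_ids, feature_ids)

    rel <- abundance / rowSums(abundance)
    if (is.null(length_factors)) {
      brel <- rel
    } else {
      if (length(length_factors) != n || any(length_factors <= 0))
        stop("length_factors must be ", n, " positive values")
      w <- abundance * rep(length_factors, each = m_samples)
      brel <- w / rowSums(w)
    }

    sdlog <- sqrt(log(1 + library_size_cv^2))
    M <- stats::rlnorm(m_samples, log(library_size_mean) - sdlog^2 / 2, sdlog)
    names(M) <- sample_ids
    expected <- M * brel
    if (any(!is.finite(expected)) || max(expected) > 2^53)
      stop("expected counts overflow; reduce abundance or library size")
    counts <- switch(noise,
      none = expected,
      poisson = matrix(stats::rpois(length(expected), expected),
                       m_samples, n),
      nb = matrix(stats::rnbinom(length(expected), mu = expected,
                                 size = 1 / nb_dispersion),
                  m_samples, n))
    dimnames(counts) <- dimnames(expected) <- list(sample_ids, feature_ids)
    names(group) <- feature_ids

    truth <- structure(list(
      abundance = abundance,
      relative_abundance = rel,
      reference_ids = ref_ids,
      reference_indices = seq_len(n_refs),
      pathway_assignment = group,
      library_sizes = M,
      condition = stats::setNames(condition, sample_ids),
      expected_counts = expected,
      config = list(m_samples = m_samples, n_conditions = n_conditions,
                    n_refs = n_refs, pathway_sizes = pathway_sizes,
                    fold_change_sd = fold_change_sd,
                    within_group_sd = within_group_sd,
                    abundance_range = abundance_range,
                    ref_abundance_range = ref_abundance_range,
                    library_size_mean = library_size_mean,
                    library_size_cv = library_size_cv, noise = noise,
                    nb_dispersion = nb_dispersion, seed = seed)),
      class = "simulation_truth")
    list(counts = counts, truth = truth)
  })
}

#' @export
print.simulation_truth <- function(x, ...) {
  cfg <- x$config
  cat("Simulated validation set: ", cfg$m_samples, " samples x ",
      length(x$pathway_assignment), " features (",
      length(x$reference_ids), " references, ",
      length(cfg$pathway_sizes), " pathway groups), noise = ", cfg$noise,
      "\n", sep = "")
  invisible(x)
}

#' Ground-truth normalization by the true references
#'
#' Normalizes a simulated count matrix against the full set of true
#' reference features; serves as the ground-truth matrix `A` for [cdev()].
#'
#' @param counts simulated count matrix.
#' @param truth `simulation_truth` from [simulate_validation_set()].
#' @return normalized matrix (samples x features).
#' @export
true_reference_normalization <- function(counts, truth) {
  if (length(truth$reference_ids) == 0) stop("reference set is empty")
  normalize_counts(counts,
                   reference_scale_factors(counts, truth$reference_ids))
}
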