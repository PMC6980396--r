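graph_from_edges <- function(n, edges) {
  corr <- diag(n)
  dimnames(corr) <- list(letters[1:n], letters[1:n])
  for (e in edges) corr[e[1], e[2]] <- corr[e[2], e[1]] <- 0.95
  build_graph(corr, threshold = 0.9)
}

clique_ids <- function(cands) {
  sort(vapply(cands, function(cd) paste(cd$feature_ids, collapse = ","),
              character(1)))
}

test_that("maximal cliques of canonical small graphs are exact", {
  # path a-b-c: the two edges
  g <- graph_from_edges(3, list(c(1, 2), c(2, 3)))
  expect_equal(clique_ids(maximal_cliques(g)), c("a,b", "b,c"))
  # triangle
  g <- graph_from_edges(3, list(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(clique_ids(maximal_cliques(g)), "a,b,c")
  # K4 minus edge (1,4): two triangles
  g <- graph_from_edges(4, list(c(1, 2), c(1, 3), c(2, 3), c(2, 4), c(3, 4)))
  expect_equal(clique_ids(maximal_cliques(g)), c("a,b,c", "b,c,d"))
  # vertex cap
  big <- graph_from_edges(5, list(c(1, 2)))
  expect_error(maximal_cliques(big, vertex_cap = 4), "detect_communities")
})

test_that("clique enumeration agrees with exhaustive subset search on random graphs", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    p <- runif(1, 0.2, 0.7)
    adj <- matrix(FALSE, n, n)
    adj[upper.tri(adj)] <- runif(n * (n - 1) / 2) < p
    adj <- adj | t(adj)
    corr <- ifelse(adj, 0.95, 0)
    diag(corr) <- 1
    dimnames(corr) <- list(paste0("v", 1:n), paste0("v", 1:n))
    got <- maximal_cliques(build_graph(corr, threshold = 0.9))
    got_sets <- sort(vapply(got, function(cd)
      paste(sort(match(cd$feature_ids, paste0("v", 1:n))), collapse = ","),
      character(1)))
    want_sets <- sort(vapply(brute_force_cliques(adj), paste,
                             character(1), collapse = ","))
    expect_equal(got_sets, want_sets)
  }
})

test_that("rank-1 residuals match closed forms and are invariant to permutation and scale", {
  expect_equal(rank1_residuals(outer(c(1, 2), c(3, 4))), 0)
  expect_equal(rank1_residuals(diag(2)), 0.5)
  expect_equal(rank1_residuals(diag(c(4, 3))), 9 / 25)
  expect_error(rank1_residuals(matrix(0, 2, 2)), "all-zero")

  set.seed(5)
  M <- matrix(rpois(60, 40), 6, 10)
  r0 <- rank1_residuals(M)
  expect_gte(r0, 0); expect_lt(r0, 1)
  expect_equal(rank1_residuals(M[sample(6), sample(10)]), r0)
  expect_equal(rank1_residuals(M * 17.3), r0)
  s2 <- svd(M)$d^2
  expect_equal(r0, 1 - s2[1] / sum(s2))
})

test_that("communities recover known block structure of a similarity matrix", {
  set.seed(3)
  blk <- function(n, r) matrix(r, n, n)
  S <- rbind(cbind(blk(10, 0.95), blk(10, 0)),
             cbind(blk(10, 0), blk(10, 0.95)))
  diag(S) <- 1
  S <- S + (matrix(rnorm(400, 0, 1e-3), 20, 20) |> (\(E) (E + t(E)) / 2)())
  diag(S) <- 1
  dimnames(S) <- list(paste0("f", 1:20), paste0("f", 1:20))
  cands <- detect_communities(S, threshold = 0.9)
  expect_length(cands, 2)
  sets <- lapply(cands, `[[`, "feature_ids")
  expect_setequal(sets[[order(vapply(sets, min, character(1)))[1]]],
                  paste0("f", 1:10))

  # all-pairs high correlation: one community, identical to the single
  # maximal clique at t = 0.9
  S1 <- matrix(0.99, 12, 12); diag(S1) <- 1
  dimnames(S1) <- list(paste0("g", 1:12), paste0("g", 1:12))
  c1 <- detect_communities(S1, threshold = 0.9)
  expect_length(c1, 1)
  cl <- maximal_cliques(build_graph(S1, threshold = 0.9))
  expect_setequal(c1[[1]]$feature_ids, cl[[1]]$feature_ids)
  expect_equal(c1[[1]]$min_internal_correlation, 0.99)

  # an isolated low-correlation feature lands in its own singleton
  S2 <- matrix(0.95, 11, 11); diag(S2) <- 1
  S2[11, 1:10] <- S2[1:10, 11] <- -0.2
  dimnames(S2) <- list(paste0("h", 1:11), paste0("h", 1:11))
  c2 <- detect_communities(S2, threshold = 0.9)
  sizes <- vapply(c2, `[[`, numeric(1), "size")
  expect_equal(sort(sizes), c(1, 10))
  expect_equal(c2[[which(sizes == 1)]]$feature_ids, "h11")

  expect_error(detect_communities(matrix(1, 1, 1)), "at least 2")
})

test_that("references are identified exactly on noiseless synthetic data", {
  sim <- simulate_validation_set(m_samples = 8, n_conditions = 8,
                                 n_refs = 20, pathway_sizes = c(15, 15),
                                 within_group_sd = 0, noise = "none",
                                 seed = 17)
  flt <- filter_features(sim$counts)$counts
  # fixture precondition: the groups' fold-change profiles are distinct
  # enough that no cross-group correlation reaches the graph threshold
  corr <- correlation_matrix(transform_counts(flt, "log2"), "pearson")
  grp <- sim$truth$pathway_assignment
  diffs <- names(grp)[grp != "reference"]
  expect_lt(max(corr[sim$truth$reference_ids, diffs]), 0.9)
  refs <- identify_references(flt, transform = "log2",
                              correlation = "pearson", seed = 17)
  expect_setequal(refs$feature_ids, sim$truth$reference_ids)
  expect_equal(precision_score(refs, sim$truth$reference_ids), 1)
  expect_lt(refs$score, 1e-12)  # reference block is exactly rank 1

  # exact-clique mode selects the same set on the same instance
  refs_exact <- identify_references(flt, transform = "log2",
                                    correlation = "pearson", mode = "exact",
                                    seed = 17)
  expect_setequal(refs_exact$feature_ids, refs$feature_ids)
  expect_equal(refs_exact$provenance, "clique")

  # candidates mixing groups with unequal fold-change profiles score
  # strictly worse than the pure reference block
  mixed <- c(sim$truth$reference_ids[1:10],
             names(sim$truth$pathway_assignment)[21:30])
  expect_gt(rank1_residuals(sim$counts[, mixed]), refs$score + 1e-8)
})

test_that("degenerate and hopeless inputs are handled explicitly", {
  # every feature an exact positive multiple of one profile: all features
  # form the reference set
  profile <- c(3, 5, 7, 11, 13)
  C <- outer(profile, c(2, 4, 1, 8, 0.5, 3))
  dimnames(C) <- list(paste0("s", 1:5), paste0("f", 1:6))
  refs <- identify_references(C, transform = "identity", mode = "exact",
                              min_size = 2)
  expect_setequal(refs$feature_ids, colnames(C))

  # independent noise with no correlated block: no reference community
  set.seed(23)
  N <- matrix(rpois(8 * 12, 50), 8, 12,
              dimnames = list(paste0("s", 1:8), paste0("f", 1:12)))
  expect_error(identify_references(N, transform = "identity",
                                   threshold = 0.999, min_size = 3,
                                   mode = "exact"),
               "no reference community")
})
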