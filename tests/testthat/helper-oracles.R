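# Independent oracles, deliberately written as blunt direct translations of
# the defining formulas (loops, no shared code with the package internals).

# All maximal cliques of an adjacency matrix by exhaustive subset search.
# Feasible only for small vertex counts.
brute_force_cliques <- function(adj) {
  n <- nrow(adj)
  stopifnot(n <= 14)
  subsets <- lapply(seq_len(2^n - 1), function(mask) {
    which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
  })
  is_clique <- vapply(subsets, function(s) {
    if (length(s) < 2) return(TRUE)
    all(adj[s, s][upper.tri(adj[s, s])])
  }, logical(1))
  cliques <- subsets[is_clique]
  maximal <- vapply(seq_along(cliques), function(i) {
    s <- cliques[[i]]
    !any(vapply(cliques, function(t2)
      length(t2) > length(s) && all(s %in% t2), logical(1)))
  }, logical(1))
  lapply(cliques[maximal], sort)
}

# Baseline scaling factors straight from the cited papers' formulas.
# counts: samples x features.
oracle_baseline <- function(counts, method) {
  m <- nrow(counts)
  libs <- numeric(m)
  for (i in 1:m) libs[i] <- sum(counts[i, ])
  gm <- function(x) exp(mean(log(x)))
  if (method == "tc") return(libs)
  if (method == "uq") {
    q <- numeric(m)
    for (i in 1:m) {
      nz <- counts[i, counts[i, ] > 0]
      q[i] <- quantile(nz, 0.75, names = FALSE, type = 7)
    }
    return(q * gm(libs) / gm(q))
  }
  if (method == "rle") {
    allpos <- which(apply(counts, 2, function(x) all(x > 0)))
    geo <- numeric(length(allpos))
    for (k in seq_along(allpos)) geo[k] <- gm(counts[, allpos[k]])
    out <- numeric(m)
    for (i in 1:m) out[i] <- median(counts[i, allpos] / geo)
    return(out)
  }
  if (method == "tmm") {
    f75 <- numeric(m)
    for (i in 1:m)
      f75[i] <- quantile(counts[i, ], 0.75, names = FALSE, type = 7) / libs[i]
    ref <- which.min(abs(f75 - mean(f75)))
    f <- numeric(m)
    for (i in 1:m) {
      if (i == ref) { f[i] <- 1; next }
      obs <- counts[i, ]; rf <- counts[ref, ]
      nO <- libs[i]; nR <- libs[ref]
      logR <- log2((obs / nO) / (rf / nR))
      absE <- (log2(obs / nO) + log2(rf / nR)) / 2
      w <- (nO - obs) / nO / obs + (nR - rf) / nR / rf
      ok <- is.finite(logR) & is.finite(absE)
      logR <- logR[ok]; absE <- absE[ok]; w <- w[ok]
      if (length(logR) == 0 || max(abs(logR)) < 1e-6) { f[i] <- 1; next }
      nn <- length(logR)
      loL <- floor(nn * 0.3) + 1; hiL <- nn + 1 - loL
      loS <- floor(nn * 0.05) + 1; hiS <- nn + 1 - loS
      rL <- rank(logR); rS <- rank(absE)
      keep <- rL >= loL & rL <= hiL & rS >= loS & rS <= hiS
      f[i] <- 2^(sum(logR[keep] / w[keep]) / sum(1 / w[keep]))
    }
    return(f * libs)
  }
  if (method == "poissonseq") {
    tot_j <- colSums(counts)
    cnt <- counts[, tot_j > 0, drop = FALSE]
    tot_j <- tot_j[tot_j > 0]
    d <- rowSums(cnt) / sum(cnt)
    kept <- NULL
    for (it in 1:20) {
      gof <- numeric(ncol(cnt))
      for (j in seq_len(ncol(cnt))) {
        e <- d * tot_j[j]
        gof[j] <- sum((cnt[, j] - e)^2 / e)
      }
      qs <- quantile(gof, c(0.25, 0.75), names = FALSE, type = 7)
      kept <- which(gof >= qs[1] & gof <= qs[2])
      d_new <- rowSums(cnt[, kept, drop = FALSE]) /
        sum(cnt[, kept, drop = FALSE])
      conv <- max(abs(d_new - d) / d) < 1e-8
      d <- d_new
      if (conv) break
    }
    return(rowSums(cnt[, kept, drop = FALSE]))
  }
  stop("unknown method")
}

# Small helper: named toy count matrix in canonical orientation.
toy_counts <- function(values, m, n,
                       sample_ids = sprintf("s%d", seq_len(m)),
                       feature_ids = sprintf("f%d", seq_len(n))) {
  matrix(values, m, n, byrow = TRUE,
         dimnames = list(sample_ids, feature_ids))
}

# Max relative departure of a matrix from "constant times `target`".
max_rel_dev_from_proportional <- function(M, target) {
  ratio <- M / target
  const <- ratio[1, 1]
  max(abs(ratio / const - 1))
}
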