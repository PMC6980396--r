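---
title: "Methods: graph-based reference identification and normalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-based reference identification and normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbnorm)
```

## The model

Write $C$ for the $m \times n$ read-count matrix (samples in rows),
$M_i = \sum_j c_{ij}$ for library sizes, and $A$ for the underlying
abundance matrix. Under the standard proportional-sampling model of
sequencing, $\mathbb{E}[c_{ij}] = M_i \, a_{ij}^{rel}$ where
$a_{ij}^{rel}$ is sample $i$'s relative abundance of feature $j$
(optionally length-weighted; a per-feature length factor $\ell_j$ changes
nothing below). A normalization is *valid* if it returns
$A^* = \mathrm{const} \times A$ — one unknown global constant is
unavoidable and harmless.

**Reference-sum scaling.** If $R$ is a set of features whose true
abundance is constant across samples, then scaling each sample by
$N_i = \sum_{j \in R} c_{ij}$ yields a valid normalization: the common
per-sample factor $M_i / \sum_k a_{ik}$ cancels. Three consequences drive
the whole design:

* any non-empty subset of true references gives the same normalization up
  to one constant (so missing references is benign);
* a single differential feature in $R$ makes the denominator vary with
  condition, invalidating the normalization (so false positives are the
  failure mode that matters — hence *precision*, not recall, is the
  headline metric);
* two references are exactly linearly correlated in expected counts,
  because both columns are multiples of the same per-sample factor. A
  reference and a differential feature are not correlated; two
  differential features are correlated only if their fold-change profiles
  coincide.

The last point turns reference finding into a graph problem: on the
thresholded correlation graph, references form a dense near-clique, and
co-expressed differential modules form the competing dense subsets.

## Discriminating references from co-expressed modules

Two criteria separate the reference community from differential ones.
First, size: biologically co-regulated modules that stay tightly
proportional across *all* conditions are rare and small, so a minimum
candidate size (`min_size`, default 10) removes incidental cliques.
Second, the **rank-1 residual**: for the candidate's raw count submatrix
$C_R$ with singular values $\sigma_1 \ge \dots \ge \sigma_d$,

$$ \mathrm{res}_1(C_R) = \frac{\sum_{i \ge 2} \sigma_i^2}{\sum_i \sigma_i^2} \in [0, 1), $$

which is 0 iff $C_R$ has rank 1. A true reference block deviates from
rank 1 only by counting noise, whose squared relative scale at count
$\lambda$ is $1/\lambda$; with reference counts in the hundreds and above
the residual sits around $10^{-5}$–$10^{-4}$. A co-expressed module
additionally carries its own regulatory spread around the shared profile,
which enters the residual quadratically and dominates counting noise. The
pipeline therefore filters candidates by minimum internal correlation
$\ge t$ and size $\ge$ `min_size`, then returns the residual argmin.
Residuals within $10^{-12}$ of the minimum are treated as exact ties
(relevant only for noiseless inputs, where several candidates hit machine
zero) and resolved toward the larger candidate, then the
lexicographically smallest ID set, so selection is deterministic.

## Candidate generation

Exact enumeration of maximal cliques (`mode = "exact"`, via igraph's
branch-and-bound enumeration, cross-checked in the tests against
exhaustive subset search) is exponential in the worst case and is guarded
by a 500-vertex cap. The default is non-overlapping community detection:
since a feature cannot be both reference and differential, a partition
suffices, and it is tolerable to miss a few references (subsets are
enough). We use affinity propagation — exemplar-based message passing —
because it consumes the correlation matrix directly as similarities, with
the conventional defaults: shared preference = median off-diagonal
similarity, damping 0.9, at most 1000 iterations, convergence declared
after 50 iterations with a stable exemplar set.

Two numerical choices matter. A deterministic, seed-controlled jitter
(~$10^{-9}$ of the similarity range) breaks the oscillations that exactly
tied similarities otherwise sustain. And the preference is nudged
infinitesimally below its nominal value, so that *exactly* uniform
similarity blocks — which make every partition of the block score equally
— resolve toward fewer exemplars instead of an arbitrary split. Both are
no-ops at realistic noise levels. If message passing still fails to
converge, the implementation falls back, with a warning, to the
deterministic partition into connected components at threshold $t$.

Candidate weights store the actual correlation values (not the constant
$t$): the minimum-internal-correlation filter needs them.

## Graph-construction parameters

* `transform`: identity, log2 (default) or log10 applied before
  correlation. Log transforms require the non-zero filter first.
  Spearman graphs are identical under all three (rank invariance), a
  property the tests exercise.
* `correlation`: Pearson (default) or Spearman (average ranks for ties).
  Thresholding is on the signed correlation; the reference signature is
  specifically *positive* linear correlation.
* `threshold` $t$: default 0.9. Higher $t$ sharpens the min-correlation
  filter but can fragment the reference community when counts are low;
  edge count is non-increasing in $t$.
* `min_size`: default 10, a compromise between robustness of the scaling
  sum (larger sets average out noise) and the risk of admitting small
  co-expression cliques.
* Correlations are computed over all samples jointly; conditions and
  replicates are not distinguished anywhere in identification.

Zero-variance feature columns have no defined correlation; they are
excluded from the graph with a warning and can only appear as singleton
candidates.

## Evaluation metrics

`precision_score` is $|X \cap R_{true}| / |X|$. `cdev` compares a
candidate normalization $A_X$ to a ground-truth normalization $A$ through
the least-squares transform $B_X = \arg\min_B \|A_X B - A\|_F$, solved
via the SVD of $A_X$ with singular values below
$\max(m,n)\,\sigma_1\,10^{-12}$ treated as zero; with fewer samples than
features ($m < n$, the usual case) this is the minimum-norm solution on
the rank-$r$ resolvable subspace. `cdev` is the spectral condition number
$\sigma_{max}/\sigma_{min}$ over the top $r$ singular values of $B_X$:
exactly 1 iff $B_X$ acts as a scalar multiple of the identity there, i.e.
iff $A_X$ is valid. The norm is chosen to make the rank-deficient case
well-defined; cdev is invariant to positive rescaling of either argument.
For very wide matrices cdev can restrict to a seeded random subset of
feature columns (default cap 2000); the subset is recorded in the result.

## The synthetic validation sets

`simulate_validation_set()` generates the structure that validation
experiments with constant-concentration spike-ins provide in real data,
with full knowledge of the truth:

* **References** (default 60): baseline abundance log-uniform on
  `[400, 20000]`, constant across all samples. With the default library
  sizes (log-normal, mean $3\times10^6$, CV 0.7 — several-fold spread, as
  across sequencing experiments) the smallest expected reference count
  stays above 100, i.e. all simulated references are "reliably detected"
  the way adequately expressed spike-ins are.
* **Differential groups**: 8 pathway-like groups drawn from a pool of 16
  templates of ~30–200 features (log-normal around 90), baseline
  abundance log-uniform on `[0.5, 5000]` (wide dynamic range). Each group
  carries a per-condition log2 fold-change profile $N(0, 1.5)$ shared by
  its members — strong, tissue-scale co-expression — plus a per-feature,
  per-condition deviation $N(0, 0.1)$ (`within_group_sd`). The deviation
  models the fact that co-regulated genes track each other strongly but
  not perfectly; with it, a differential module's count submatrix is
  measurably further from rank 1 than the reference block, which is what
  the selection step exploits. Setting `within_group_sd = 0` produces
  exactly proportional modules, the regime used by the algebraic
  invariant tests (where reference and module blocks tie at residual zero
  and selection falls to the size tie-break).
* **Samples**: 41 samples in 13 conditions by default (near-even split);
  counts are Poisson draws around $M_i b^{rel}_{ij}$ by default, negative
  binomial with configurable dispersion or exact expectations
  (`noise = "none"`, real-valued so Theorem-style identities hold to
  machine precision) as alternatives. Everything is reproducible from
  `seed`.

What the generator does *not* emulate: length/GC bias beyond a static
per-feature factor, batch effects, outlier samples, zero inflation, and
correlated noise between features. Passing the simulation suite therefore
shows that the method recovers references when the model's correlation
structure holds at realistic noise levels — not that it is robust to
artifacts outside that model. The method also inherently needs enough
samples for correlations to be estimable (the implementation warns below
3; in practice dozens).

## Problem sizes and determinism

The shipped test and acceptance workloads use 20 simulated sets of 41
samples × ~900 features (~600–700 after filtering), where one full
identification run (correlation matrix + affinity propagation + scoring)
takes a few seconds; the six-configuration precision sweep over 20 sets
completes in a few minutes on one core. All stochastic steps — simulation,
jitter, random subsets — derive from explicit integer seeds, and the CLI
exposes a single `--seed` flag.

## Known limitations

* Affinity propagation can fail to converge on unfavorable correlation
  structures (the connected-components fallback then applies and is
  noisier); on real compendia the community step, not the theory, is the
  fragile part.
* When *every* large correlated block is differential (no references
  survive filtering), the method reports "no reference community found"
  rather than guessing; lowering $t$ or `min_size` is the documented
  escape hatch.
* Precision of identification, not recall, is what the scaling theory
  needs; reported reference sets may be conservative subsets of the true
  stable features.
* Scaling returns real-valued normalized matrices; count-based DE
  pipelines that need integer counts should instead consume the factors
  as offsets.
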