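# gbnorm: graph-based between-sample normalization of RNA-seq counts

Between-sample normalization rescales each sample of an RNA-seq count
matrix so that fold changes reflect biology rather than sequencing depth.
Classical global-scaling methods (total count, upper quartile, TMM,
median-of-ratios, PoissonSeq) all assume that *most* features are not
differentially expressed. That assumption breaks down exactly where
normalization matters most: large, heterogeneous collections of profiles
(many tissues, cell types, conditions), where the majority of genes vary.

`gbnorm` takes a different route. Features whose true abundance is constant
across samples ("references", not necessarily housekeeping genes) are
mutually linearly correlated in raw read counts, because each one tracks
the same per-sample factor (sequencing depth over total RNA content).
Features that respond to condition are not correlated with the references,
and are correlated with each other only when they share a fold-change
profile. So in a graph whose vertices are features and whose edges connect
pairs with correlation at least *t*, the references form a dense
(near-complete) subgraph — and they can be found without any prior
knowledge of which features are stable.

For m samples and n features with counts c<sub>ij</sub>:

1. **Filter** features to those reliably detected in every sample
   (non-zero, optionally above each sample's lower quartile).
2. **Graph**: compute pairwise feature correlations (Pearson or Spearman,
   on identity/log2/log10-transformed counts) and connect pairs with
   cor ≥ t (default: log2 + Pearson, t = 0.9).
3. **Candidates**: enumerate maximal cliques exactly (small graphs), or
   partition the correlation matrix with affinity propagation (the default;
   it consumes the similarity matrix directly and needs no preset cluster
   count). Candidates with minimum internal correlation below t or fewer
   than `min_size` features are dropped.
4. **Select** the candidate whose raw count submatrix C<sub>R</sub> is
   closest to rank 1, by the rank-1 residual
   Σ<sub>i≥2</sub> σ<sub>i</sub>² / Σ<sub>i</sub> σ<sub>i</sub>²
   of its singular values — 0 exactly when the candidate behaves as a true
   reference block.
5. **Scale**: the factor for sample i is
   N<sub>i</sub> = Σ<sub>j∈R</sub> c<sub>ij</sub>, and the normalized
   matrix is a\*<sub>ij</sub> = c<sub>ij</sub>/N<sub>i</sub>, which equals
   the true abundance up to one global constant whenever R contains only
   genuine references (any non-empty subset of them suffices; a single
   contaminating differential feature invalidates this).

Quality is measured against a known ground truth by **precision** (the
fraction of identified features that are true references) and by **cdev**,
the spectral condition number of the least-squares matrix
B<sub>X</sub> = argmin ‖A<sub>X</sub>B − A‖ that maps a candidate
normalization A<sub>X</sub> onto the ground-truth normalization A;
cdev = 1 means A<sub>X</sub> is a valid normalization, larger is worse.

## Worked example

Simulate a validation set with known references (41 samples, ~60 reference
features, 8 co-expressed differential pathway groups, Poisson counting
noise), then recover the references and normalize:

```r
library(gbnorm)

sim <- simulate_validation_set(seed = 11)   # 41 x 609 counts + ground truth
res <- gbnorm(sim$counts, seed = 11)        # filter -> identify -> scale
res$references
#> Reference set (community): 60 features
#>   rank-1 residual: 2.159e-05 | min internal correlation: 0.9974
#>   config: log2 + pearson, t = 0.9, min_size = 10

precision_score(res$references, sim$truth$reference_ids)
#> [1] 1

A <- true_reference_normalization(sim$counts, sim$truth)  # ground truth
cdev(res$normalized, A)
#> [1] 1
cdev(normalize_counts(sim$counts, baseline_factors(sim$counts, "tc")), A)
#> [1] 176.805
cdev(normalize_counts(sim$counts, baseline_factors(sim$counts, "tmm")), A)
#> [1] 3360.204
```

All 60 identified features are true references (precision 1), so the
reference-based factors reproduce the ground-truth normalization exactly
(cdev = 1). Total-count and TMM factors are driven far off by the
co-expressed differential groups that dominate this matrix (cdev ≫ 1) —
the regime the graph-based method is designed for.

The same pipeline is available from the shell (`inst/cli/gbnorm`):

```sh
gbnorm simulate --seed 11 --out sim/
gbnorm identify --counts sim/counts.tsv --out ident/
gbnorm normalize --counts sim/counts.tsv --refs ident/references.txt --out norm/
gbnorm evaluate --identified ident/references.txt --truth sim/truth_references.txt --out eval/
gbnorm baselines --counts sim/counts.tsv --out base/
```

Reference identification and scaling are deliberately separate stages, so
references discovered on one matrix can scale another (e.g. identify on a
large compendium, normalize a spiked subset).

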