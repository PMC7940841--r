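# pl21gpca

Robust, sparse, graph-regularized principal component analysis for gene
expression matrices, with a clustering evaluation harness and gene
co-expression network modules.

## The problem

Bulk and single-cell expression matrices are tall and thin (p genes ≫ n
samples), noisy, and outlier-prone, and their samples usually lie near a
low-dimensional manifold that reflects tumor subtype or tissue of origin.
Ordinary PCA is sensitive to outliers (squared loss), selects no genes, and
ignores the sample manifold. This package fits the factorization

$$
\min_{U,V}\ \|X - UV^\top\|_p \;+\; \lambda\,\|U\|_{2,1}
\;+\; \alpha\,\mathrm{Tr}(V^\top L V)
\qquad \text{s.t. } V^\top V = I,
$$

where X is the p × n expression matrix, U (p × k) the gene loadings, V
(n × k) the orthonormal sample embedding, and:

* ‖·‖ₚ with 0 < p < 1 is the Lp quasi-norm — a heavy-tail-tolerant
  reconstruction loss;
* ‖U‖₂,₁ = Σᵢ ‖uᵢ·‖₂ zeroes whole gene rows (gene selection);
* L = D − W is the Laplacian of a k′-nearest-neighbor sample graph, so
  Tr(VᵀLV) keeps similar samples close in the embedding.

The non-convex objective is solved by an augmented-Lagrangian
alternating-direction scheme: a reweighted ridge step for U, a smallest-k
eigenvector step for V (orthonormal by construction), a generalized
p-shrinkage step for the residual E, then multiplier and penalty updates.
Tumor samples are clustered by K-means on the rows of V; differentially
expressed genes are ranked by the absolute row sums of U and connected into
Pearson-correlation co-expression modules.

Intended users: computational biologists benchmarking subtype-clustering
pipelines and anyone needing a robust, manifold-aware PCA with built-in gene
selection for p ≫ n data.

## Worked example

Generate the built-in planted benchmark (3000 genes × 80 samples, four
sample classes, Gaussian noise of variance 0.6), fit with defaults
(k = 4, p = 0.5, λ = α = 100, k′ = round(√80) = 9, binary kNN weighting),
and evaluate the embedding by 50 K-means restarts:

```r
library(pl21gpca)

sim <- simulate_expression(noise_variance = 0.6, seed = 7)
fit <- pl21gpca_fit(sim$X, pl21gpca_config(k = 4))
fit
#> pl21gpca_fit: 3000 genes x 80 samples, k = 4
#>   96 sweeps, converged (final relative residual 9.66e-08)

report <- kmeans_harness(fit$V, k = 4, prior = sim$labels, n_runs = 50, seed = 7)
report
#> clustering_report over 50 K-means restarts
#>   ACC  mean 100.00%  max 100.00%
#>   NMI  mean 100.00%  max 100.00%
```

The fit converged: the constraint residual ‖E − X + UVᵀ‖F/‖X‖F fell below
the 1e-7 tolerance in 96 sweeps. Every one of the 50 K-means restarts on the
four embedding coordinates recovered the planted 4 × 20 class structure
exactly (mean and max accuracy and normalized mutual information all 100%):
under this generator's unclipped-noise protocol the planted block offsets
dominate the noise even at the highest benchmark variance, so the sample
graph and embedding separate the classes cleanly (see the methods vignette
for a discussion of noise protocols and when degradation appears).

Downstream, `rank_genes(fit$U)` scores genes by |loading| row sums,
`pcc_adjacency()` builds the thresholded |Pearson| network on the top genes,
and `extract_modules()` returns its connected components and node degrees;
`run_pipeline(run_config(...))` chains all stages and writes TSV/JSON
artifacts. The same operations are scriptable via
`exec/pl21gpca <simulate|fit|evaluate|network|run>`.

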