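# scspectral

Clustering single-cell proteomics data by **graph contrastive learning with
spectral polynomial filters**.

## The problem

Single-cell mass-spectrometry proteomics produces cell-by-protein abundance
matrices that are small, noisy, and riddled with missing values, and whose
cells vary in acquisition depth. The robust route to cell-type discovery is
graph-based: join cells whose protein profiles correlate, then learn node
embeddings on that graph. Standard graph-convolutional encoders only see
shallow neighborhoods, and stacking layers over-smooths the signal away.

`scspectral` replaces the stacked encoder with a single **K-hop spectral
propagation**

&nbsp;&nbsp;&nbsp;&nbsp;H = Σₖ cₖ Âᵏ X W,&nbsp;&nbsp; k = 0…K,

where Â = D^(−1/2)(A+I)D^(−1/2) is the self-loop-normalized adjacency
(spectrum in [−1, 1]) and the scalar coefficients cₖ are *learnable* but
*initialized from an explicit low-pass spectral filter* g(ω):

* random walk with restart: g(ω) = (1−α)/(1−αω)
* heat kernel: g(ω) = e^(T(ω−1))
* zeroth-order beta kernel: g(ω) = (K+1)((1+ω)/2)^K

Closed-form coefficient schemes (Neumann truncation, Taylor expansion,
binomial expansion) are provided, but the package's distinctive machinery is
**polynomial interpolation of any filter on Chebyshev nodes, stabilized by
Arnoldi orthonormalization**: the naive Vandermonde system is exponentially
ill-conditioned (Gram condition number > 10⁹ at degree 12), while the
Arnoldi basis is conditioned at ~1 and recovers monomial coefficients
through a Hessenberg back-substitution, exactly at the nodes to 1e−8 up to
degree 24. Embeddings are trained with a symmetric InfoNCE objective over
two stochastically augmented graph views and evaluated with ARI / NMI /
purity / silhouette under an eight-seed mean ± 95% CI protocol.

A synthetic-corpus generator (planted cell types, dropout,
acquisition-depth variation, batch effects) makes the whole pipeline
testable without external data.

## Worked example

```r
library(scspectral)

corpus <- generate_corpus(synthetic_spec(seed = 1))
corpus$expression
#> <expr_matrix> 180 cells x 300 proteins (35.0% missing)

graph <- build_similarity_graph(corpus$expression, graph_build_config(h = 0.15))
graph
#> <cell_graph> 180 nodes, 1004 edges

feats <- standardize_proteins(impute_missing(corpus$expression)$values)
fit <- train_gcl(feats, graph,
                 encoder_config(K = 6, D = 64, init = "heat_interpolated", t = 2),
                 train_cfg = train_config(epochs = 100, seed = 1))
fit
#> <gcl_fit> spectral encoder, 180 cells x 64 dims, 100 epochs, final loss 4.1788

pred <- kmeans_cluster(fit$embedding, k = 3, seed = 1)
evaluate_clustering(fit$embedding, corpus$truth$label, pred)
#> # A tibble: 1 × 4
#>     ari    asw   nmi    ps
#>   <dbl>  <dbl> <dbl> <dbl>
#> 1 0.351 0.0987 0.414 0.622
```

The adjusted Rand index (0.35) says the k-means partition of the learned
embedding recovers a substantial part of the planted three-type structure
on this deliberately hard corpus (35% missing entries, depth variation of
1 log unit); purity 0.62 means a majority vote over predicted clusters
labels 62% of cells correctly. On the same corpus PCA + k-means sits near
ARI 0 because Euclidean distances are dominated by per-cell acquisition
depth, to which the correlation graph is invariant.

The learned coefficients stay interpretable — compare them with their
filter initialization:

```r
interpolate_coefficients(spectral_filter("heat", t = 2), K = 6)
#> <coef_vector> K=6 scheme=heat_interpolated
#> [1] 0.135340 0.270890 0.270720 0.178320 0.089700 0.041245 0.013304

head(tidy(fit), 4)
#> # A tibble: 4 × 3
#>   order initial learned
#>   <int>   <dbl>   <dbl>
#> 1     0   0.135  0.203
#> 2     1   0.271  0.190
#> 3     2   0.271  0.183
#> 4     3   0.178  0.0951
```

`run_pipeline(run_config(...), out_dir = "...")` drives the whole thing
(synthesize/load → graph → train → cluster → evaluate) and writes
embeddings, metrics, coefficient dumps, training logs and a manifest;
`sweep_grid()` produces long-format tables over filter-parameter or
graph-threshold grids. A thin CLI with subcommands
(`simulate`, `build-graph`, `interpolate`, `train`, `cluster`, `evaluate`,
`run`, `sweep`) is installed at `exec/scspectral`.

See `vignettes/spectral-filter-gcl.Rmd` for the model, its assumptions,
the numerical design of the Arnoldi interpolation, and what the synthetic
generator does and does not emulate.

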