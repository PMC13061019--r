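# shared fixtures, all generated in code

# the default desk-scale corpus used by the benchmark-style tests
default_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_corpus(synthetic_spec(seed = 1L))
    cache
  }
})

# tiny deterministic expression matrix: 3 cells x 4 proteins with
# hand-checkable pairwise Pearson correlations (see test-graphio.R)
toy_expression <- function() {
  expression_matrix(
    rbind(
      c(1, 2, 3, 4),
      c(2, 3, 5, 7),
      c(4, 3, 3, 1)
    ),
    cell_ids = c("a", "b", "c"),
    protein_ids = paste0("p", 1:4)
  )
}

# explicit Pearson correlation, written out so tests do not lean on cor()
pearson_by_hand <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# two-triangle graph: two 3-cliques joined by nothing (communities 1-3, 4-6)
two_clique_graph <- function() {
  cell_graph(6L, rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)))
}

# path graph on n nodes
path_graph <- function(n) {
  cell_graph(n, cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L))
}

# small random graph + features for propagation equivalence checks
random_instance <- function(n, d, p_edge = 0.2, seed = 1L) {
  withr::with_seed(seed, {
    pairs <- t(combn(n, 2L))
    keep <- runif(nrow(pairs)) < p_edge
    g <- cell_graph(n, pairs[keep, , drop = FALSE])
    X <- matrix(rnorm(n * d), n, d)
    list(graph = g, X = X)
  })
}

# dense polynomial-of-adjacency oracle: sum_k c_k A^k X by explicit powers
dense_propagate_oracle <- function(X, A_dense, coeffs) {
  out <- coeffs[1L] * X
  P <- diag(nrow(A_dense))
  for (k in seq_len(length(coeffs) - 1L)) {
    P <- P %*% A_dense
    out <- out + coeffs[k + 1L] * (P %*% X)
  }
  out
}

# the benchmark filter-parameter grids used by interpolation exactness checks
grid_filters <- function() {
  c(
    lapply(c(0.05, 0.275, 0.5, 0.725, 0.95),
           function(a) spectral_filter("rwr", alpha = a)),
    lapply(1:5, function(tt) spectral_filter("heat", t = tt)),
    lapply(2:6, function(k) spectral_filter("beta", k = k))
  )
}
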