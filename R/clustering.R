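#' Cluster labels
#'
#' @param assignment integer vector of cluster memberships (any coding;
#'   re-coded to 1..n_clusters in order of first appearance).
#' @return An object of class `cluster_labels` with fields `assignment` and
#'   `n_clusters`.
#' @export
cluster_labels <- function(assignment) {
  a <- as.integer(factor(assignment, levels = unique(assignment)))
  structure(list(assignment = a, n_clusters = max(a)), class = "cluster_labels")
}

as_assignment <- function(x) {
  if (inherits(x, "cluster_labels")) x$assignment else as.integer(as.factor(x))
}

#' K-means clustering of an embedding
#'
#' Seeded Lloyd iterations ([stats::kmeans()] with multiple restarts);
#' `k` conventionally equals the known number of cell types in benchmark
#' settings.
#'
#' @param H numeric embedding matrix, cells in rows.
#' @param k number of clusters, `1 <= k <= N`.
#' @param seed integer seed.
#' @param nstart random restarts (default 10).
#' @return A `cluster_labels`.
#' @export
kmeans_cluster <- function(H, k, seed = 1L, nstart = 10L) {
  H <- as.matrix(H)
  stop_if_not_scalar_number(k, "k", lo = 1, hi = nrow(H), integer = TRUE)
  if (k == nrow(H)) {
    return(cluster_labels(seq_len(nrow(H))))  # every point its own cluster
  }
  fit <- with_seed(seed, stats::kmeans(H, centers = k, nstart = nstart,
                                       iter.max = 100L))
  cluster_labels(fit$cluster)
}

#' Louvain community detection
#'
#' Modularity-maximizing Louvain partition of a cell graph (or, via
#' [louvain_cluster_embedding()], of the kNN graph of an embedding — the
#' single-cell convention, since Louvain needs a graph).
#'
#' @param g a `cell_graph` with at least one node.
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed integer seed (Louvain's greedy pass visits nodes in random
#'   order).
#' @return A `cluster_labels`.
#' @export
louvain_cluster <- function(g, resolution = 1, seed = 1L) {
  stopifnot(inherits(g, "cell_graph"))
  if (g$n_nodes < 1L) rlang::abort("empty graph")
  ig <- igraph::make_empty_graph(n = g$n_nodes, directed = FALSE)
  if (n_edges(g) > 0L) {
    ig <- igraph::add_edges(ig, as.vector(t(g$edges)))
  }
  comm <- with_seed(seed,
    igraph::cluster_louvain(ig, resolution = resolution))
  cluster_labels(igraph::membership(comm))
}

#' @rdname louvain_cluster
#' @param H numeric embedding matrix.
#' @param k neighbours for the kNN graph (default 15).
#' @export
louvain_cluster_embedding <- function(H, k = 15L, resolution = 1, seed = 1L) {
  louvain_cluster(knn_graph(H, k), resolution = resolution, seed = seed)
}

#' PCA dimensionality reduction
#'
#' Top principal components by explained variance (centered, unscaled;
#' deterministic up to sign). The classical front end for the K-means and
#' Louvain baselines.
#'
#' @param X an `expr_matrix` without missing values, or a numeric matrix.
#' @param n_components number of components, at most `min(N, d)`.
#' @return numeric N x n_components score matrix.
#' @export
pca_reduce <- function(X, n_components) {
  m <- feature_matrix(X)
  stop_if_not_scalar_number(n_components, "n_components", lo = 1,
                            hi = min(dim(m)), integer = TRUE)
  stats::prcomp(m, center = TRUE, scale. = FALSE,
                rank. = n_components)$x[, seq_len(n_components), drop = FALSE]
}
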