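#' Undirected, unweighted cell-to-cell similarity graph
#'
#' Edges are stored once as a two-column integer matrix with `i < j`
#' (1-based node indices); no self-loops, no duplicates.
#'
#' @param n_nodes number of cells.
#' @param edges two-column integer matrix of node pairs (any orientation;
#'   canonicalized internally), or `NULL` for an edgeless graph.
#' @param cell_ids optional character identifiers carried through file IO.
#' @return An object of class `cell_graph`.
#' @export
cell_graph <- function(n_nodes, edges = NULL, cell_ids = NULL) {
  stop_if_not_scalar_number(n_nodes, "n_nodes", lo = 1, integer = TRUE)
  n_nodes <- as.integer(n_nodes)
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(integer(), ncol = 2L)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2L)
    if (any(edges < 1L) || any(edges > n_nodes)) {
      rlang::abort("edge endpoints must lie in [1, n_nodes]")
    }
    if (any(edges[, 1L] == edges[, 2L])) {
      rlang::abort("self-loops are not allowed")
    }
    edges <- t(apply(edges, 1L, sort))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  if (!is.null(cell_ids) && length(cell_ids) != n_nodes) {
    rlang::abort("`cell_ids` length must equal `n_nodes`")
  }
  structure(
    list(n_nodes = n_nodes, edges = edges,
         cell_ids = if (is.null(cell_ids)) NULL else as.character(cell_ids)),
    class = "cell_graph"
  )
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("<cell_graph> %d nodes, %d edges\n", x$n_nodes, n_edges(x)))
  invisible(x)
}

#' @rdname cell_graph
#' @param g a `cell_graph`.
#' @export
n_edges <- function(g) nrow(g$edges)

#' Graph construction configuration
#'
#' @param h correlation threshold: an edge joins two cells whose profile
#'   correlation is `>= h` (inclusive).
#' @param correlation `"pearson"` (default, the convention for cell-to-cell
#'   similarity in single-cell proteomics) or `"spearman"`.
#' @param standardize z-score each protein over its observed entries before
#'   correlating (default `TRUE`); the raw scale is available by switching
#'   this off.
#' @return An object of class `graph_build_config`.
#' @export
graph_build_config <- function(h = 0.15,
                               correlation = c("pearson", "spearman"),
                               standardize = TRUE) {
  stop_if_not_scalar_number(h, "h", lo = -1, hi = 1)
  structure(
    list(h = h, correlation = match.arg(correlation),
         standardize = isTRUE(standardize)),
    class = "graph_build_config"
  )
}

#' Build the cell-to-cell similarity graph by correlation thresholding
#'
#' Computes all pairwise correlations between cell profiles over jointly
#' observed proteins (pairwise-complete observations; missing entries never
#' enter the computation) and joins cells whose correlation reaches the
#' threshold `h`. A pair with fewer than 3 jointly observed proteins, or a
#' zero-variance profile, yields an undefined correlation, which is treated
#' as 0 with a warning.
#'
#' @param x an `expr_matrix` with at least 2 cells.
#' @param cfg a [graph_build_config()].
#' @return A `cell_graph`.
#' @export
build_similarity_graph <- function(x, cfg = graph_build_config()) {
  stopifnot(inherits(x, "expr_matrix"), inherits(cfg, "graph_build_config"))
  if (n_cells(x) < 2L) {
    rlang::abort("need at least 2 cells to build a similarity graph")
  }
  v <- x$values
  if (cfg$standardize) v <- standardize_proteins(v)
  # pairs with < 3 jointly observed proteins are censored to NA below
  joint <- tcrossprod(!is.na(v) * 1)
  cc <- suppressWarnings(
    stats::cor(t(v), use = "pairwise.complete.obs", method = cfg$correlation)
  )
  cc[joint < 3L] <- NA
  diag(cc) <- NA
  und <- !is.finite(cc)
  diag(und) <- FALSE
  if (any(und)) {
    rlang::warn(sprintf(
      "%d cell pair(s) had undefined correlation (<3 jointly observed proteins or zero variance); treated as 0",
      sum(und) / 2
    ))
    cc[und] <- 0
  }
  sel <- which(upper.tri(cc) & cc >= cfg$h, arr.ind = TRUE)
  cell_graph(n_cells(x), edges = sel, cell_ids = x$cell_ids)
}

#' Symmetrically normalized adjacency operator
#'
#' Forms \eqn{\hat A = D^{-1/2} (A + I) D^{-1/2}} where `D` is the degree
#' matrix of the self-loop-augmented adjacency `A + I`. The self-loops
#' guarantee positive degrees (isolated nodes get \eqn{\hat A_{ii} = 1}) and
#' place the spectrum inside \eqn{[-1, 1]}, the interval on which the
#' spectral filters are defined. Stored sparsely.
#'
#' @param g a `cell_graph`.
#' @return An object of class `norm_adjacency` with fields `mat` (a sparse
#'   symmetric `Matrix`) and `n_nodes`.
#' @export
normalize_adjacency <- function(g) {
  stopifnot(inherits(g, "cell_graph"))
  n <- g$n_nodes
  if (n_edges(g) > 0L) {
    a <- Matrix::sparseMatrix(
      i = c(g$edges[, 1L], g$edges[, 2L], seq_len(n)),
      j = c(g$edges[, 2L], g$edges[, 1L], seq_len(n)),
      x = 1, dims = c(n, n)
    )
  } else {
    a <- Matrix::Diagonal(n)
  }
  dinv <- 1 / sqrt(Matrix::rowSums(a))
  ahat <- Matrix::Diagonal(n, dinv) %*% a %*% Matrix::Diagonal(n, dinv)
  structure(
    list(mat = methods::as(ahat, "generalMatrix"), n_nodes = n),
    class = "norm_adjacency"
  )
}

#' @export
print.norm_adjacency <- function(x, ...) {
  cat(sprintf("<norm_adjacency> %d nodes, %d nonzeros\n",
              x$n_nodes, length(x$mat@x)))
  invisible(x)
}

#' Dense matrix of a normalized adjacency (small graphs only)
#'
#' @param a a `norm_adjacency`.
#' @return base dense matrix.
#' @export
as_dense <- function(a) {
  stopifnot(inherits(a, "norm_adjacency"))
  as.matrix(a$mat)
}

#' k-nearest-neighbour graph of an embedding
#'
#' Builds the undirected kNN graph (union of directed neighbourhoods) in
#' Euclidean distance; the single-cell convention for running community
#' detection on an embedding.
#'
#' @param H numeric embedding matrix, cells in rows.
#' @param k neighbours per cell (default 15).
#' @return A `cell_graph`.
#' @export
knn_graph <- function(H, k = 15L) {
  n <- nrow(H)
  k <- min(as.integer(k), n - 1L)
  if (k < 1L) rlang::abort("need at least 2 points for a kNN graph")
  d2 <- as.matrix(stats::dist(H))
  diag(d2) <- Inf
  nb <- t(apply(d2, 1L, function(row) order(row)[seq_len(k)]))
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nb)))
  cell_graph(n, edges = edges)
}
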