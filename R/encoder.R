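#' Spectral convolution encoder configuration
#'
#' The encoder decouples feature embedding from propagation: one linear map
#' of the node features followed by a single K-hop polynomial propagation
#' \eqn{H = \sum_{k=0}^K c_k \hat A^k X W} with learnable scalar coefficients
#' \eqn{c_k} shared across channels. The coefficients are initialized exactly
#' from a chosen scheme (closed-form, interpolated, or random), which is what
#' makes the filter choice an explicit, inspectable hyperparameter.
#'
#' @param K propagation order (default 6, the small-world depth used
#'   throughout).
#' @param D embedding dimension (default 64).
#' @param interval interpolation interval for `*_interpolated` schemes
#'   (default `c(-0.9, 0.9)`).
#' @param init coefficient initialization: a `coef_vector`, or a scheme
#'   string among `"rwr_truncated"`, `"rwr_interpolated"`, `"heat_taylor"`,
#'   `"heat_interpolated"`, `"beta_direct"`, `"random"`.
#' @param alpha,t filter parameters consumed by the rwr/heat schemes.
#' @param learn_coefficients train the propagation coefficients alongside the
#'   weights (default `TRUE`).
#' @param activation output nonlinearity applied in the contrastive head
#'   (`"prelu"` default, `"relu"`, or `"identity"`); never applied inside the
#'   propagation itself.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(K = 6L, D = 64L, interval = c(-0.9, 0.9),
                           init = "heat_interpolated", alpha = 0.9, t = 2,
                           learn_coefficients = TRUE,
                           activation = c("prelu", "relu", "identity")) {
  stop_if_not_scalar_number(K, "K", lo = 1, integer = TRUE)
  stop_if_not_scalar_number(D, "D", lo = 1, integer = TRUE)
  stopifnot(length(interval) == 2L, interval[1L] < interval[2L])
  structure(
    list(K = as.integer(K), D = as.integer(D), interval = interval,
         init = init, alpha = alpha, t = t,
         learn_coefficients = isTRUE(learn_coefficients),
         activation = match.arg(activation)),
    class = "encoder_config"
  )
}

#' Materialize the initial coefficient vector of a configuration
#'
#' @param cfg an [encoder_config()].
#' @param seed seed used only by the `"random"` scheme.
#' @return A `coef_vector` of length `K + 1`.
#' @export
initial_coefficients <- function(cfg, seed = 1L) {
  if (inherits(cfg$init, "coef_vector")) {
    if (poly_degree(cfg$init) != cfg$K) {
      rlang::abort("supplied coefficient vector does not match K")
    }
    return(cfg$init)
  }
  l <- cfg$interval[1L]; u <- cfg$interval[2L]
  switch(cfg$init,
    rwr_truncated = rwr_truncated_coefficients(cfg$alpha, cfg$K),
    rwr_interpolated = interpolate_coefficients(
      spectral_filter("rwr", alpha = cfg$alpha), cfg$K, l, u),
    heat_taylor = heat_taylor_coefficients(cfg$t, cfg$K),
    heat_interpolated = interpolate_coefficients(
      spectral_filter("heat", t = cfg$t), cfg$K, l, u),
    beta_direct = beta_coefficients(cfg$K),
    random = random_coefficients(cfg$K, seed),
    rlang::abort(sprintf("unknown init scheme '%s'", cfg$init))
  )
}

#' Initialize encoder parameters
#'
#' Glorot-uniform linear map, coefficients set bitwise to the configured
#' initialization, PReLU slope 0.25, and an identity-leaning Glorot linear
#' projector for the contrastive head.
#'
#' @param input_dim number of input features (proteins).
#' @param cfg an [encoder_config()].
#' @param seed integer seed for the weight draws.
#' @return An object of class `encoder_state` with fields `W` (d x D), `c`
#'   (numeric K+1), `a` (PReLU slope), `Wp` (D x D projector), plus the
#'   initialization metadata.
#' @export
init_encoder_state <- function(input_dim, cfg, seed = 1L) {
  init <- initial_coefficients(cfg, seed)
  with_seed(seed, {
    lim_w <- sqrt(6 / (input_dim + cfg$D))
    W <- matrix(stats::runif(input_dim * cfg$D, -lim_w, lim_w),
                input_dim, cfg$D)
    lim_p <- sqrt(6 / (2 * cfg$D))
    Wp <- matrix(stats::runif(cfg$D * cfg$D, -lim_p, lim_p), cfg$D, cfg$D)
    structure(
      list(W = W, c = init$coeffs, a = 0.25, Wp = Wp,
           init_coeffs = init, cfg = cfg),
      class = "encoder_state"
    )
  })
}

#' K-hop polynomial propagation
#'
#' Computes \eqn{\sum_{k=0}^K c_k \hat A^k X} by K successive sparse
#' applications of \eqn{\hat A}; neither \eqn{\hat A^k} nor the filtered
#' operator is ever materialized densely.
#'
#' @param X numeric feature matrix (nodes x channels).
#' @param a_hat a `norm_adjacency` (or a plain matrix for testing).
#' @param c numeric coefficient vector, length K+1.
#' @return a dense matrix of the same shape as `X`.
#' @export
spectral_propagate <- function(X, a_hat, c) {
  if (inherits(c, "coef_vector")) c <- c$coeffs
  X <- as.matrix(X)
  A <- if (inherits(a_hat, "norm_adjacency")) a_hat$mat else a_hat
  if (nrow(X) != nrow(A)) rlang::abort("feature rows must match graph nodes")
  H <- c[1L] * X
  Xp <- X
  for (k in seq_len(length(c) - 1L)) {
    Xp <- as.matrix(A %*% Xp)
    H <- H + c[k + 1L] * Xp
  }
  if (any(!is.finite(H))) {
    rlang::abort("non-finite values during propagation (exploding coefficients?)")
  }
  H
}

# propagated powers P_k = A^k X for k = 0..K, kept for coefficient gradients
propagate_powers <- function(X, A, K) {
  out <- vector("list", K + 1L)
  out[[1L]] <- X
  for (k in seq_len(K)) {
    out[[k + 1L]] <- as.matrix(A %*% out[[k]])
  }
  out
}

#' Forward pass of the spectral encoder
#'
#' \eqn{H = \sum_k c_k \hat A^k (X W)}; deterministic given the state. The
#' output is the raw embedding — the contrastive head (activation, projector,
#' normalization) lives in the training loop, so embeddings handed to
#' clustering are exactly what the propagation produced.
#'
#' @param X an `expr_matrix` with no missing entries (see
#'   [impute_missing()]), or a plain numeric matrix of node features.
#' @param graph a `cell_graph` or a precomputed `norm_adjacency`.
#' @param state an `encoder_state`.
#' @return numeric N x D embedding matrix.
#' @export
encoder_forward <- function(X, graph, state) {
  feats <- feature_matrix(X)
  a_hat <- as_norm_adjacency(graph)
  if (ncol(feats) != nrow(state$W)) {
    rlang::abort(sprintf("feature dim %d does not match W (%d rows)",
                         ncol(feats), nrow(state$W)))
  }
  spectral_propagate(feats %*% state$W, a_hat, state$c)
}

#' Stacked GCN baseline
#'
#' The standard depth-L graph convolution
#' \eqn{H^{(l+1)} = \sigma(\hat A H^{(l)} W^{(l)})} (no activation after the
#' last layer). Serves both as the adjacency-matrix contrastive baseline
#' (2 layers) and as the subject of the over-smoothing depth sweep.
#'
#' @param X features as in [encoder_forward()].
#' @param graph a `cell_graph` or `norm_adjacency`.
#' @param n_layers depth, at least 1.
#' @param D output (and hidden) dimension.
#' @param weights optional list of weight matrices, one per layer; drawn
#'   Glorot-uniform from `seed` when omitted.
#' @param seed seed for the weight draws.
#' @param activation `"relu"` (default) or `"identity"` hidden nonlinearity.
#' @return numeric N x D embedding matrix.
#' @export
gcn_baseline_forward <- function(X, graph, n_layers = 2L, D = 64L,
                                 weights = NULL, seed = 1L,
                                 activation = c("relu", "identity")) {
  stop_if_not_scalar_number(n_layers, "n_layers", lo = 1, integer = TRUE)
  activation <- match.arg(activation)
  feats <- feature_matrix(X)
  a_hat <- as_norm_adjacency(graph)
  weights <- weights %||% gcn_weights(ncol(feats), D, n_layers, seed)
  if (length(weights) != n_layers) {
    rlang::abort("`weights` must hold one matrix per layer")
  }
  H <- feats
  for (l in seq_len(n_layers)) {
    H <- as.matrix(a_hat$mat %*% H) %*% weights[[l]]
    if (l < n_layers && activation == "relu") H <- relu(H)
  }
  H
}

gcn_weights <- function(d_in, D, n_layers, seed) {
  with_seed(seed, {
    dims <- c(d_in, rep(D, n_layers))
    lapply(seq_len(n_layers), function(l) {
      lim <- sqrt(6 / (dims[l] + dims[l + 1L]))
      matrix(stats::runif(dims[l] * dims[l + 1L], -lim, lim),
             dims[l], dims[l + 1L])
    })
  })
}

#' Over-smoothing depth profile
#'
#' Runs the stacked GCN at each requested depth (deeper models extend the
#' shallower ones with additional layers drawn from the same seed) and
#' records the mean pairwise cosine similarity of embedding rows — the
#' collapse diagnostic that rises towards 1 as depth washes out cell
#' identity.
#'
#' @param X,graph as in [gcn_baseline_forward()].
#' @param depths integer vector of depths (default 2:8).
#' @param D embedding dimension.
#' @param seed weight seed.
#' @return A tibble with columns `depth`, `mean_cosine`, and the embedding
#'   list-column `embedding`.
#' @export
oversmoothing_profile <- function(X, graph, depths = 2:8, D = 64L, seed = 1L) {
  weights <- gcn_weights(ncol(feature_matrix(X)), D, max(depths), seed)
  purrr::map_dfr(sort(depths), function(dep) {
    H <- gcn_baseline_forward(X, graph, n_layers = dep, D = D,
                              weights = weights[seq_len(dep)])
    tibble::tibble(depth = dep, mean_cosine = mean_pairwise_cosine(H),
                   embedding = list(H))
  })
}

feature_matrix <- function(X) {
  if (inherits(X, "expr_matrix")) {
    if (anyNA(X$values)) {
      rlang::abort("features contain missing values; run impute_missing() first")
    }
    X$values
  } else {
    as.matrix(X)
  }
}

as_norm_adjacency <- function(graph) {
  if (inherits(graph, "norm_adjacency")) return(graph)
  if (inherits(graph, "cell_graph")) return(normalize_adjacency(graph))
  rlang::abort("`graph` must be a cell_graph or norm_adjacency")
}
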