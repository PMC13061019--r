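#' Stochastic graph augmentation configuration
#'
#' Two independent corruptions generate the contrastive views: each edge is
#' removed with `edge_drop_rate` and each feature column (protein) is masked
#' to zero with `feature_mask_rate`. The defaults (0.2 / 0.2) are the
#' standard choices of the GRACE lineage of node-level contrastive learners.
#'
#' @param edge_drop_rate probability in \eqn{[0, 1)} of dropping each edge.
#' @param feature_mask_rate probability in \eqn{[0, 1)} of masking each
#'   feature column.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(edge_drop_rate = 0.2, feature_mask_rate = 0.2) {
  stop_if_not_scalar_number(edge_drop_rate, "edge_drop_rate", lo = 0, hi = 1)
  stop_if_not_scalar_number(feature_mask_rate, "feature_mask_rate", lo = 0, hi = 1)
  if (edge_drop_rate >= 1 || feature_mask_rate >= 1) {
    rlang::abort("augmentation rates must be < 1")
  }
  structure(list(edge_drop_rate = edge_drop_rate,
                 feature_mask_rate = feature_mask_rate),
            class = "augmentation_config")
}

#' Create an augmented view of a graph and its features
#'
#' @param graph a `cell_graph`.
#' @param X numeric node-feature matrix.
#' @param cfg an [augmentation_config()].
#' @param seed optional seed; when given the view is reproducible, otherwise
#'   the caller's RNG stream is consumed.
#' @return list with `graph` (a `cell_graph`) and `X` (masked features).
#' @export
augment <- function(graph, X, cfg = augmentation_config(), seed = NULL) {
  stopifnot(inherits(graph, "cell_graph"), inherits(cfg, "augmentation_config"))
  draw <- function() {
    keep <- stats::runif(n_edges(graph)) >= cfg$edge_drop_rate
    g2 <- cell_graph(graph$n_nodes, graph$edges[keep, , drop = FALSE],
                     graph$cell_ids)
    X2 <- as.matrix(X)
    masked <- stats::runif(ncol(X2)) < cfg$feature_mask_rate
    X2[, masked] <- 0
    list(graph = g2, X = X2)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Symmetric InfoNCE contrastive loss
#'
#' Normalized-temperature cross entropy over node pairs: rows of both
#' embeddings are L2-normalized; for each node the positive is its
#' counterpart in the other view, and all other nodes of both views are
#' negatives. The mean over nodes of both directions is returned.
#'
#' @param H1,H2 numeric N x D embeddings of the two views.
#' @param tau temperature, positive (default 0.5).
#' @return a single number.
#' @export
contrastive_loss <- function(H1, H2, tau = 0.5) {
  stop_if_not_scalar_number(tau, "tau", lo = 0, open = TRUE)
  if (!identical(dim(H1), dim(H2))) rlang::abort("views must have equal shape")
  nce_loss_grad(row_normalize(as.matrix(H1)),
                row_normalize(as.matrix(H2)), tau, grad = FALSE)$loss
}

# loss and (optionally) gradients wrt the *normalized* embeddings U1, U2
nce_loss_grad <- function(U1, U2, tau, grad = TRUE) {
  n <- nrow(U1)
  S12 <- U1 %*% t(U2) / tau
  S11 <- U1 %*% t(U1) / tau
  S22 <- U2 %*% t(U2) / tau
  E12 <- exp(S12); E11 <- exp(S11); E22 <- exp(S22)
  diag(E11) <- 0; diag(E22) <- 0
  den1 <- rowSums(E12) + rowSums(E11)
  den2 <- colSums(E12) + rowSums(E22)   # direction 2 uses S21 = t(S12)
  loss <- mean((-diag(S12) + log(den1)) + (-diag(S12) + log(den2))) / 2
  if (!is.finite(loss)) rlang::abort("contrastive loss diverged (non-finite)")
  if (!grad) return(list(loss = loss))
  w <- 1 / (2 * n)
  P12 <- E12 / den1; P11 <- E11 / den1
  P21 <- t(E12) / den2; P22 <- E22 / den2
  d12 <- w * (P12 - diag(n))            # dL/dS12 (direction 1)
  d11 <- w * P11
  d21 <- w * (P21 - diag(n))            # dL/dS21 (direction 2)
  d22 <- w * P22
  dU1 <- (d12 %*% U2 + (d11 + t(d11)) %*% U1 + t(d21) %*% U2) / tau
  dU2 <- (t(d12) %*% U1 + (d22 + t(d22)) %*% U2 + d21 %*% U1) / tau
  list(loss = loss, dU1 = dU1, dU2 = dU2)
}

# backward through row L2-normalization: U = P / ||P||
row_normalize_backward <- function(dU, U, norms) {
  (dU - U * rowSums(dU * U)) / norms
}

#' Training configuration for graph contrastive learning
#'
#' @param epochs number of full-batch epochs (default 100; 0 returns the
#'   untrained encoder output).
#' @param learning_rate Adam step size for the weights (default 1e-3).
#' @param coefficient_learning_rate Adam step size for the propagation
#'   coefficients; defaults to `learning_rate`.
#' @param tau InfoNCE temperature (default 0.5).
#' @param projector use a linear projection head before the loss
#'   (default `TRUE`); embeddings returned for clustering are always taken
#'   before the head.
#' @param seed integer seed governing weight init and per-epoch augmentation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, learning_rate = 1e-3,
                         coefficient_learning_rate = learning_rate,
                         tau = 0.5, projector = TRUE, seed = 1L) {
  stop_if_not_scalar_number(epochs, "epochs", lo = 0, integer = TRUE)
  stop_if_not_scalar_number(learning_rate, "learning_rate", lo = 0, open = TRUE)
  stop_if_not_scalar_number(tau, "tau", lo = 0, open = TRUE)
  structure(
    list(epochs = as.integer(epochs), learning_rate = learning_rate,
         coefficient_learning_rate = coefficient_learning_rate,
         tau = tau, projector = isTRUE(projector), seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Train cell embeddings by graph contrastive learning
#'
#' Full-batch two-view contrastive training. Each epoch draws two augmented
#' views, runs the encoder on both, applies the contrastive head (PReLU,
#' optional linear projector, row normalization) and takes one Adam step on
#' the symmetric InfoNCE loss. Gradients are analytic (the model is a linear
#' map, K+1 scalars, a projector and a PReLU slope — small enough that
#' hand-derived backpropagation is exact and fast). Final embeddings are
#' computed on the un-augmented graph.
#'
#' @param X an `expr_matrix` without missing entries, or a feature matrix.
#' @param graph a `cell_graph`.
#' @param encoder_cfg an [encoder_config()].
#' @param aug_cfg an [augmentation_config()].
#' @param train_cfg a [train_config()].
#' @param model `"spectral"` (the polynomial-filter encoder) or
#'   `"adjacency-gcn"` (two-layer GCN baseline).
#' @return An object of class `gcl_fit`: `embedding` (N x D), `state`
#'   (trained parameters), `log` (tibble: epoch, loss, coefficient
#'   trajectory), `init_coeffs`, and the configs.
#' @export
train_gcl <- function(X, graph,
                      encoder_cfg = encoder_config(),
                      aug_cfg = augmentation_config(),
                      train_cfg = train_config(),
                      model = c("spectral", "adjacency-gcn")) {
  model <- match.arg(model)
  stopifnot(inherits(graph, "cell_graph"))
  feats <- feature_matrix(X)
  if (nrow(feats) != graph$n_nodes) {
    rlang::abort("feature rows must match graph nodes")
  }
  with_seed(train_cfg$seed, {
    if (model == "spectral") {
      state <- init_encoder_state(ncol(feats), encoder_cfg,
                                  seed = stats::runif(1, 1, 2^30))
    } else {
      w <- gcn_weights(ncol(feats), encoder_cfg$D, 2L,
                       seed = stats::runif(1, 1, 2^30))
      state <- structure(
        list(W1 = w[[1L]], W2 = w[[2L]], a = 0.25,
             Wp = diag(encoder_cfg$D), cfg = encoder_cfg),
        class = "gcn_state"
      )
    }
    opt <- adam_new(param_list(state, model, train_cfg))
    log_rows <- vector("list", train_cfg$epochs)
    for (ep in seq_len(train_cfg$epochs)) {
      v1 <- augment(graph, feats, aug_cfg)
      v2 <- augment(graph, feats, aug_cfg)
      step <- gcl_step(state, v1, v2, train_cfg, model)
      opt <- adam_update(opt, step$grads)
      state <- apply_params(state, opt$params, model, train_cfg)
      log_rows[[ep]] <- c(epoch = ep, loss = step$loss,
                          if (model == "spectral") stats::setNames(
                            state$c, paste0("c", seq_along(state$c) - 1L)))
    }
    H <- if (model == "spectral") {
      encoder_forward(feats, graph, state)
    } else {
      gcn_baseline_forward(feats, graph, n_layers = 2L, D = encoder_cfg$D,
                           weights = list(state$W1, state$W2))
    }
    log <- if (train_cfg$epochs > 0) {
      tibble::as_tibble(do.call(rbind, log_rows))
    } else {
      tibble::tibble(epoch = integer(), loss = numeric())
    }
    structure(
      list(embedding = H, state = state, log = log,
           init_coeffs = if (model == "spectral") state$init_coeffs else NULL,
           model = model, encoder_cfg = encoder_cfg,
           aug_cfg = aug_cfg, train_cfg = train_cfg),
      class = "gcl_fit"
    )
  })
}

#' @export
print.gcl_fit <- function(x, ...) {
  cat(sprintf(
    "<gcl_fit> %s encoder, %d cells x %d dims, %d epochs%s\n",
    x$model, nrow(x$embedding), ncol(x$embedding), nrow(x$log),
    if (nrow(x$log)) sprintf(", final loss %.4f", x$log$loss[nrow(x$log)]) else ""
  ))
  invisible(x)
}

# ---- forward/backward of one contrastive step --------------------------------

gcl_step <- function(state, v1, v2, train_cfg, model) {
  f1 <- view_forward(state, v1, train_cfg, model)
  f2 <- view_forward(state, v2, train_cfg, model)
  lg <- nce_loss_grad(f1$U, f2$U, train_cfg$tau)
  g1 <- view_backward(state, f1, lg$dU1, train_cfg, model)
  g2 <- view_backward(state, f2, lg$dU2, train_cfg, model)
  grads <- purrr::map2(g1, g2, `+`)
  list(loss = lg$loss, grads = grads)
}

view_forward <- function(state, view, train_cfg, model) {
  A <- normalize_adjacency(view$graph)$mat
  if (model == "spectral") {
    Z <- view$X %*% state$W
    powers <- propagate_powers(Z, A, length(state$c) - 1L)
    H <- Reduce(`+`, purrr::map2(state$c, powers, `*`))
  } else {
    pre1 <- as.matrix(A %*% (view$X %*% state$W1))
    H1 <- relu(pre1)
    AH1 <- as.matrix(A %*% H1)
    H <- AH1 %*% state$W2
    powers <- NULL
  }
  act <- switch(state$cfg$activation,
    prelu = prelu(H, state$a),
    relu = relu(H),
    identity = H
  )
  P <- if (train_cfg$projector) act %*% state$Wp else act
  norms <- sqrt(rowSums(P^2))
  if (any(norms == 0)) rlang::abort("zero-norm projected row; cannot normalize")
  U <- P / norms
  out <- list(A = A, X = view$X, H = H, act = act, P = P, norms = norms, U = U,
              powers = powers)
  if (model == "adjacency-gcn") {
    out$pre1 <- pre1; out$H1 <- H1; out$AH1 <- AH1
  }
  out
}

view_backward <- function(state, fw, dU, train_cfg, model) {
  dP <- row_normalize_backward(dU, fw$U, fw$norms)
  if (train_cfg$projector) {
    dWp <- crossprod(fw$act, dP)
    dact <- dP %*% t(state$Wp)
  } else {
    dWp <- state$Wp * 0
    dact <- dP
  }
  neg <- fw$H <= 0
  dH <- switch(state$cfg$activation,
    prelu = ifelse(neg, state$a * dact, dact),
    relu = ifelse(neg, 0, dact),
    identity = dact
  )
  da <- if (state$cfg$activation == "prelu") sum(dact[neg] * fw$H[neg]) else 0
  if (model == "spectral") {
    cc <- state$c
    K <- length(cc) - 1L
    dc <- vapply(seq_along(cc), function(k) sum(fw$powers[[k]] * dH), 0)
    # dZ = sum_k c_k A^k dH, Horner over the symmetric operator
    dZ <- cc[K + 1L] * dH
    for (k in rev(seq_len(K))) {
      dZ <- as.matrix(fw$A %*% dZ)
      dZ <- dZ + cc[k] * dH
    }
    list(W = crossprod(fw$X, dZ), c = dc, a = da, Wp = dWp)
  } else {
    dW2 <- crossprod(fw$AH1, dH)
    dAH1 <- dH %*% t(state$W2)
    dH1 <- as.matrix(fw$A %*% dAH1)   # A symmetric
    dpre1 <- ifelse(fw$pre1 > 0, dH1, 0)
    dW1 <- crossprod(as.matrix(fw$A %*% fw$X), dpre1)
    list(W1 = dW1, W2 = dW2, a = da, Wp = dWp)
  }
}

# ---- parameter plumbing + Adam ----------------------------------------------

param_list <- function(state, model, train_cfg) {
  if (model == "spectral") {
    p <- list(W = state$W, c = state$c, a = state$a, Wp = state$Wp)
    if (!state$cfg$learn_coefficients) p$c <- NULL
  } else {
    p <- list(W1 = state$W1, W2 = state$W2, a = state$a, Wp = state$Wp)
  }
  if (!train_cfg$projector) p$Wp <- NULL
  if (state$cfg$activation != "prelu") p$a <- NULL
  attr(p, "lr") <- vapply(names(p), function(nm) {
    if (nm == "c") train_cfg$coefficient_learning_rate else train_cfg$learning_rate
  }, 0)
  p
}

apply_params <- function(state, params, model, train_cfg) {
  for (nm in names(params)) state[[nm]] <- params[[nm]]
  state
}

adam_new <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(params = params, lr = attr(params, "lr"),
       m = purrr::map(params, ~ .x * 0), v = purrr::map(params, ~ .x * 0),
       t = 0L, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_update <- function(opt, grads) {
  opt$t <- opt$t + 1L
  for (nm in names(opt$params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - opt$beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - opt$beta2^opt$t)
    opt$params[[nm]] <- opt$params[[nm]] -
      opt$lr[[nm]] * mhat / (sqrt(vhat) + opt$eps)
  }
  opt
}
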