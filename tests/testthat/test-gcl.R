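test_that("identity augmentation returns the input view", {
  inst <- random_instance(10, 4, seed = 1)
  v <- augment(inst$graph, inst$X, augmentation_config(0, 0), seed = 1)
  expect_equal(v$graph$edges, inst$graph$edges)
  expect_equal(v$X, inst$X)
})

test_that("edge dropping is binomially calibrated and seeded", {
  inst <- random_instance(60, 2, p_edge = 0.5, seed = 2)
  m <- n_edges(inst$graph)
  rate <- 0.9
  kept <- vapply(1:30, function(s) {
    n_edges(augment(inst$graph, inst$X, augmentation_config(rate, 0), seed = s)$graph)
  }, 0L)
  expected <- m * (1 - rate)
  tol <- 3 * sqrt(m * rate * (1 - rate) / 30)
  expect_lt(abs(mean(kept) - expected), tol)

  v1 <- augment(inst$graph, inst$X, augmentation_config(0.3, 0.3), seed = 7)
  v2 <- augment(inst$graph, inst$X, augmentation_config(0.3, 0.3), seed = 7)
  expect_identical(v1, v2)
})

test_that("feature masking zeroes whole protein columns", {
  inst <- random_instance(10, 50, seed = 3)
  v <- augment(inst$graph, inst$X, augmentation_config(0, 0.4), seed = 5)
  zeroed <- apply(v$X == 0, 2, all)
  expect_gt(sum(zeroed), 5)
  expect_equal(v$X[, !zeroed], inst$X[, !zeroed])
})

test_that("contrastive loss matches the two-node hand computation", {
  H <- diag(2)  # orthogonal one-hot rows
  # identical views, tau = 1: denominator per node = e^1 + e^0 + e^0
  expect_equal(contrastive_loss(H, H, tau = 1), log(exp(1) + 2) - 1)
  # symmetry in the two views
  H2 <- matrix(c(0.3, 1, -0.2, 0.5), 2, 2)
  expect_equal(contrastive_loss(H, H2, 0.5), contrastive_loss(H2, H, 0.5))
  # misaligned positives cost more than aligned ones
  expect_gt(contrastive_loss(H, H[2:1, ], tau = 1),
            contrastive_loss(H, H, tau = 1))
  expect_error(contrastive_loss(matrix(0, 2, 2), H, 0.5), "zero-norm")
})

test_that("analytic gradients match finite differences", {
  set.seed(99)
  n <- 7; d <- 5; D <- 4
  g <- cell_graph(n, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6),
                           c(1, 6), c(2, 5), c(6, 7), c(3, 7)))
  X <- matrix(rnorm(n * d) + 1, n, d)
  tc <- train_config(tau = 0.7)
  v1 <- augment(g, X, augmentation_config(0.2, 0.2), seed = 21)
  v2 <- augment(g, X, augmentation_config(0.2, 0.2), seed = 22)
  loss_of <- function(st, model) {
    f1 <- scspectral:::view_forward(st, v1, tc, model)
    f2 <- scspectral:::view_forward(st, v2, tc, model)
    scspectral:::nce_loss_grad(f1$U, f2$U, tc$tau, grad = FALSE)$loss
  }
  eps <- 1e-6

  enc <- encoder_config(K = 2, D = D, init = coefficient_vector(c(0.3, 0.5, 0.2)))
  st <- init_encoder_state(d, enc, seed = 3)
  step <- scspectral:::gcl_step(st, v1, v2, tc, "spectral")
  for (nm in c("W", "c", "a", "Wp")) {
    num <- st[[nm]]
    for (i in seq_along(num)) {
      sp <- st; sp[[nm]][i] <- sp[[nm]][i] + eps
      sm <- st; sm[[nm]][i] <- sm[[nm]][i] - eps
      num[i] <- (loss_of(sp, "spectral") - loss_of(sm, "spectral")) / (2 * eps)
    }
    expect_lt(max(abs(num - step$grads[[nm]])), 1e-7, label = nm)
  }

  w <- scspectral:::gcn_weights(d, D, 2, 5)
  stg <- structure(list(W1 = w[[1]], W2 = w[[2]], a = 0.25, Wp = diag(D),
                        cfg = enc), class = "gcn_state")
  stepg <- scspectral:::gcl_step(stg, v1, v2, tc, "adjacency-gcn")
  for (nm in c("W1", "W2", "a", "Wp")) {
    num <- stg[[nm]]
    for (i in seq_along(num)) {
      sp <- stg; sp[[nm]][i] <- sp[[nm]][i] + eps
      sm <- stg; sm[[nm]][i] <- sm[[nm]][i] - eps
      num[i] <- (loss_of(sp, "adjacency-gcn") - loss_of(sm, "adjacency-gcn")) /
        (2 * eps)
    }
    expect_lt(max(abs(num - stepg$grads[[nm]])), 1e-7, label = paste("gcn", nm))
  }
})

test_that("zero-epoch training returns the untrained encoder output", {
  inst <- random_instance(12, 6, seed = 4)
  enc <- encoder_config(K = 3, D = 5, init = "beta_direct")
  fit <- train_gcl(inst$X, inst$graph, enc,
                   train_cfg = train_config(epochs = 0, seed = 5))
  expect_equal(fit$embedding, encoder_forward(inst$X, inst$graph, fit$state))
  expect_equal(nrow(fit$log), 0L)
})

test_that("training runs are seed-deterministic and reduce the loss", {
  corp <- generate_corpus(synthetic_spec(cells_per_type = 20, n_proteins = 100,
                                         n_marker_proteins_per_type = 10,
                                         seed = 8))
  g <- build_similarity_graph(corp$expression)
  Z <- standardize_proteins(impute_missing(corp$expression)$values)
  enc <- encoder_config(K = 4, D = 16, init = "heat_interpolated", t = 2)

  f1 <- train_gcl(Z, g, enc, train_cfg = train_config(epochs = 30, seed = 3))
  f2 <- train_gcl(Z, g, enc, train_cfg = train_config(epochs = 30, seed = 3))
  expect_identical(f1$embedding, f2$embedding)
  expect_identical(f1$log, f2$log)

  # optimization sanity across seeds: median final loss below median first loss
  drops <- vapply(1:5, function(s) {
    fit <- train_gcl(Z, g, enc, train_cfg = train_config(epochs = 30, seed = s))
    fit$log$loss[1] - fit$log$loss[30]
  }, 0)
  expect_gt(median(drops), 0)

  # coefficient trajectory starts bitwise at the initialization
  fit <- train_gcl(Z, g, enc, train_cfg = train_config(epochs = 2, seed = 1))
  expect_identical(fit$init_coeffs$coeffs,
                   initial_coefficients(enc)$coeffs)
  expect_true(all(paste0("c", 0:4) %in% names(fit$log)))
})

test_that("learned coefficients stay near their initialization", {
  corp <- generate_corpus(synthetic_spec(cells_per_type = 20, n_proteins = 100,
                                         n_marker_proteins_per_type = 10,
                                         seed = 9))
  g <- build_similarity_graph(corp$expression)
  Z <- standardize_proteins(impute_missing(corp$expression)$values)
  fit_h <- train_gcl(Z, g, encoder_config(K = 6, D = 16, init = "heat_interpolated"),
                     train_cfg = train_config(epochs = 40, seed = 1))
  fit_b <- train_gcl(Z, g, encoder_config(K = 6, D = 16, init = "beta_direct"),
                     train_cfg = train_config(epochs = 40, seed = 1))
  drift_h <- sqrt(sum((fit_h$state$c - fit_h$init_coeffs$coeffs)^2))
  gap_schemes <- sqrt(sum((fit_h$init_coeffs$coeffs - fit_b$init_coeffs$coeffs)^2))
  expect_lt(drift_h, gap_schemes)
})

test_that("gcl fit exposes tidy and glance views", {
  inst <- random_instance(10, 5, seed = 6)
  fit <- train_gcl(inst$X, inst$graph,
                   encoder_config(K = 2, D = 4, init = "beta_direct"),
                   train_cfg = train_config(epochs = 3, seed = 2))
  td <- tidy(fit)
  expect_equal(td$order, 0:2)
  expect_equal(td$initial, beta_coefficients(2)$coeffs)
  gl <- glance(fit)
  expect_equal(gl$epochs, 3L)
  expect_equal(gl$scheme, "beta_direct")
})
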