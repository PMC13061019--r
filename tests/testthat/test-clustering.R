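test_that("k-means separates well-separated clouds and respects k", {
  X <- withr::with_seed(1, rbind(matrix(rnorm(40, 0), ncol = 2),
                                 matrix(rnorm(40, 10), ncol = 2)))
  truth <- rep(1:2, each = 20)
  cl <- kmeans_cluster(X, 2, seed = 1)
  expect_equal(ari(truth, cl), 1)
  expect_equal(kmeans_cluster(X, nrow(X), seed = 1)$n_clusters, nrow(X))
  expect_identical(kmeans_cluster(X, 2, seed = 3)$assignment,
                   kmeans_cluster(X, 2, seed = 3)$assignment)
  expect_error(kmeans_cluster(X, nrow(X) + 1), "k")
})

test_that("Louvain finds the two cliques and beats singletons on modularity", {
  g <- two_clique_graph()
  cl <- louvain_cluster(g, seed = 1)
  expect_equal(cl$n_clusters, 2L)
  expect_equal(ari(rep(1:2, each = 3), cl), 1)
  ig <- igraph::make_graph(t(g$edges), n = 6, directed = FALSE)
  expect_gte(igraph::modularity(ig, cl$assignment),
             igraph::modularity(ig, 1:6))
})

test_that("PCA reduction matches the dense covariance eigendecomposition", {
  X <- withr::with_seed(2, matrix(rnorm(40 * 6), 40, 6))
  red <- pca_reduce(X, 3)
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  want <- Xc %*% ev$vectors[, 1:3]
  for (j in 1:3) {
    expect_equal(abs(red[, j]), abs(want[, j]), tolerance = 1e-8)
  }
  vars <- apply(pca_reduce(X, 6), 2, var)
  expect_true(all(diff(vars) <= 1e-12))
  # perfectly 1-D data reconstructs from one component
  line <- outer(seq_len(20), c(1, 2, 3))
  expect_equal(apply(pca_reduce(line, 3), 2, var)[2:3], c(PC2 = 0, PC3 = 0),
               tolerance = 1e-20)
})

test_that("agreement metrics match hand contingency computations", {
  expect_equal(ari(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(purity(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)

  truth <- c(0, 0, 1, 1)
  pred <- c(0, 1, 0, 1)
  expect_equal(ari(truth, pred), -0.5)
  expect_equal(purity(truth, pred), 0.5)

  # invariance to label permutation of either argument
  perm <- c(2, 2, 1, 1)
  expect_equal(ari(truth, perm), 1)
  expect_equal(nmi(truth, perm), 1)
  expect_error(ari(c(1, 2), c(1, 2, 3)), "length")
})

test_that("nmi uses arithmetic-mean normalization", {
  truth <- c(1, 1, 1, 2, 2, 2)
  pred <- c(1, 1, 2, 2, 3, 3)
  # hand computation over the 2x3 contingency table
  tab <- table(truth, pred) / 6
  px <- rowSums(tab); py <- colSums(tab)
  mi <- sum(ifelse(tab > 0, tab * log(tab / outer(px, py)), 0))
  hx <- -sum(px * log(px)); hy <- -sum(py * log(py))
  expect_equal(nmi(truth, pred), mi / ((hx + hy) / 2), tolerance = 1e-10)
})

test_that("silhouette matches the 4-point line hand computation", {
  H <- matrix(c(0, 1, 5, 6), 4, 1)
  labels <- c(1, 1, 2, 2)
  # outer points: a = 1, b = (5+6)/2 = 5.5 -> s = 4.5/5.5
  # inner points: a = 1, b = (4+5)/2 = 4.5 -> s = 3.5/4.5
  expect_equal(asw(H, labels), ((4.5 / 5.5) + (3.5 / 4.5)) / 2, tolerance = 1e-12)
  expect_error(asw(H, c(1, 1, 1, 1)), "single cluster")
})

test_that("silhouette behaves at its limits", {
  far <- rbind(matrix(rnorm(20, 0, 0.01), ncol = 2),
               matrix(rnorm(20, 1000, 0.01), ncol = 2))
  expect_gt(asw(far, rep(1:2, each = 10)), 0.99)
  for (s in 1:5) {
    cloud <- withr::with_seed(s, matrix(rnorm(120), ncol = 2))
    labs <- withr::with_seed(s + 100, sample(1:3, 60, replace = TRUE))
    expect_lt(abs(asw(cloud, labs)), 0.1)
  }
})

test_that("evaluation tuple and the seed harness aggregate correctly", {
  X <- withr::with_seed(3, rbind(matrix(rnorm(30, 0), ncol = 3),
                                 matrix(rnorm(30, 8), ncol = 3)))
  truth <- rep(1:2, each = 10)
  ev <- evaluate_clustering(X, truth, kmeans_cluster(X, 2, seed = 1))
  expect_named(ev, c("ari", "asw", "nmi", "ps"))
  expect_equal(ev$ari, 1)

  # identical per-seed values give a zero-width CI
  rep0 <- seed_sweep(function(s) tibble::tibble(ari = 0.5), seeds = 1:8)
  expect_equal(rep0$summary$ci_lo, 0.5)
  expect_equal(rep0$summary$ci_hi, 0.5)

  # hand-checked t-interval over eight fixed values
  vals <- c(0.1, 0.2, 0.15, 0.3, 0.25, 0.2, 0.1, 0.3)
  rep1 <- seed_sweep(function(s) tibble::tibble(m = vals[s]), seeds = 1:8)
  half <- qt(0.975, 7) * sd(vals) / sqrt(8)
  expect_equal(rep1$summary$mean, mean(vals))
  expect_equal(rep1$summary$ci_hi - rep1$summary$mean, half, tolerance = 1e-12)

  # report serialization round-trips the per-seed table
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metrics_report(rep1, path)
  back <- read_metrics_report(path)
  expect_equal(back$per_seed$m, vals)
  expect_equal(back$summary$mean, rep1$summary$mean)
})
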