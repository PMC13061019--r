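#' Clustering agreement and validity metrics
#'
#' The four evaluation criteria used throughout: Adjusted Rand Index
#' (chance-corrected pair-counting agreement, in \eqn{[-1, 1]}), Normalized
#' Mutual Information (arithmetic-mean normalization, in \eqn{[0, 1]}),
#' Purity Score (mean majority-class fraction over predicted clusters, in
#' \eqn{[0, 1]}), and the internal Average Silhouette Width (in
#' \eqn{[-1, 1]}).
#'
#' @param truth,pred partitions of the same cells: integer/factor vectors or
#'   `cluster_labels`.
#' @return a single number.
#' @export
ari <- function(truth, pred) {
  check_partitions(truth, pred)
  mclust::adjustedRandIndex(as_assignment(truth), as_assignment(pred))
}

#' @rdname ari
#' @export
nmi <- function(truth, pred) {
  check_partitions(truth, pred)
  t <- as_assignment(truth); p <- as_assignment(pred)
  if (length(unique(t)) == 1L && length(unique(p)) == 1L) return(1)
  igraph::compare(t, p, method = "nmi")
}

#' @rdname ari
#' @export
purity <- function(truth, pred) {
  check_partitions(truth, pred)
  tab <- table(as_assignment(pred), as_assignment(truth))
  sum(apply(tab, 1L, max)) / length(as_assignment(truth))
}

check_partitions <- function(truth, pred) {
  t <- as_assignment(truth); p <- as_assignment(pred)
  if (length(t) != length(p)) rlang::abort("partitions differ in length")
  if (length(t) < 1L) rlang::abort("empty partitions")
  invisible(NULL)
}

#' Average silhouette width of a labelled embedding
#'
#' Mean over cells of \eqn{(b - a)/\max(a, b)} in Euclidean distance, where
#' `a` is the mean intra-cluster distance and `b` the smallest mean distance
#' to another cluster; cells in singleton clusters contribute 0.
#'
#' @param H numeric embedding matrix.
#' @param labels a partition with at least 2 clusters.
#' @return a single number in \eqn{[-1, 1]}.
#' @export
asw <- function(H, labels) {
  a <- as_assignment(labels)
  if (length(unique(a)) < 2L) {
    rlang::abort("silhouette is undefined for a single cluster")
  }
  sil <- cluster::silhouette(a, stats::dist(as.matrix(H)))
  mean(sil[, "sil_width"])
}

#' Evaluate a clustering against ground truth
#'
#' @param H embedding the clustering was computed on (for the silhouette).
#' @param truth ground-truth cell types.
#' @param pred predicted partition.
#' @param asw_on `"pred"` (default: internal validity of the predicted
#'   partition) or `"truth"` (silhouette of the true types in the
#'   embedding).
#' @return A one-row tibble with columns `ari`, `asw`, `nmi`, `ps`.
#' @export
evaluate_clustering <- function(H, truth, pred, asw_on = c("pred", "truth")) {
  asw_on <- match.arg(asw_on)
  tibble::tibble(
    ari = ari(truth, pred),
    asw = asw(H, if (asw_on == "pred") pred else truth),
    nmi = nmi(truth, pred),
    ps = purity(truth, pred)
  )
}

#' Multi-seed experiment harness
#'
#' Runs a pipeline function once per seed and aggregates every numeric
#' metric it returns as mean with a 95% t-distribution confidence interval —
#' the standard eight-seed reporting protocol.
#'
#' @param pipeline a function of one argument (the seed) returning a one-row
#'   data frame / tibble of numeric metrics.
#' @param seeds integer vector of seeds (default `1:8`).
#' @return An object of class `metrics_report`: a list with `per_seed`
#'   (tibble, one row per seed) and `summary` (tibble: metric, mean, ci_lo,
#'   ci_hi, n_seeds).
#' @export
seed_sweep <- function(pipeline, seeds = 1:8) {
  per_seed <- purrr::map_dfr(seeds, function(s) {
    row <- tibble::as_tibble(pipeline(s))
    dplyr::mutate(row, seed = s, .before = 1L)
  })
  metrics_report(per_seed)
}

#' @rdname seed_sweep
#' @param per_seed tibble with a `seed` column and numeric metric columns.
#' @export
metrics_report <- function(per_seed) {
  per_seed <- tibble::as_tibble(per_seed)
  metric_cols <- setdiff(names(per_seed)[vapply(per_seed, is.numeric, TRUE)],
                         "seed")
  summary <- purrr::map_dfr(metric_cols, function(mc) {
    ci <- t_ci(per_seed[[mc]])
    tibble::tibble(metric = mc, mean = ci[["mean"]], ci_lo = ci[["ci_lo"]],
                   ci_hi = ci[["ci_hi"]], n_seeds = nrow(per_seed))
  })
  structure(list(per_seed = per_seed, summary = summary),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d seeds\n", nrow(x$per_seed)))
  print(x$summary)
  invisible(x)
}

#' Write/read a metrics report as delimited text
#'
#' One record per seed plus summary records, in a single machine-readable
#' TSV with a `record` column (`"seed"` or `"summary"`).
#'
#' @param report a `metrics_report`.
#' @param path file path.
#' @export
write_metrics_report <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  per_seed <- dplyr::mutate(report$per_seed, record = "seed", .before = 1L)
  long <- tidyr::pivot_longer(per_seed, -c("record", "seed"),
                              names_to = "metric", values_to = "value")
  summ <- dplyr::mutate(
    tidyr::pivot_longer(report$summary, c("mean", "ci_lo", "ci_hi"),
                        names_to = "stat", values_to = "value"),
    record = "summary", .before = 1L
  )
  out <- dplyr::bind_rows(
    dplyr::mutate(long, stat = "value"),
    dplyr::select(summ, "record", "metric", "stat", "value",
                  n_seeds = "n_seeds")
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_metrics_report
#' @export
read_metrics_report <- function(path) {
  df <- tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE))
  seeds <- dplyr::filter(df, .data$record == "seed")
  per_seed <- tidyr::pivot_wider(
    dplyr::select(seeds, "seed", "metric", "value"),
    names_from = "metric", values_from = "value"
  )
  metrics_report(per_seed)
}

#' @importFrom rlang .data
NULL
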