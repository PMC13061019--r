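#' Pipeline run configuration
#'
#' Bundles every stage of the pipeline — input (a file or a synthetic
#' corpus), graph construction, filter/initialization choice, encoder,
#' contrastive training and evaluation — into a single validated object that
#' round-trips through YAML.
#'
#' @param input `"synthetic"` (default) or a path to an expression matrix
#'   readable by [read_expression()].
#' @param labels_path optional two-column (cell_id, label) file with ground
#'   truth for evaluation when `input` is a file.
#' @param synthetic a [synthetic_spec()] used when `input == "synthetic"`.
#' @param h correlation threshold for the similarity graph.
#' @param correlation `"pearson"` or `"spearman"`.
#' @param family filter family: `"rwr"`, `"heat"`, `"beta"`, or `"none"`
#'   (for the `random` and `adjacency-gcn` variants).
#' @param variant `"truncated"` (rwr), `"taylor"` (heat), `"interpolated"`
#'   (rwr/heat), `"direct"` (beta), `"random"`, or `"adjacency-gcn"`;
#'   validated against `family` before any compute.
#' @param alpha,t,K filter parameters (restart probability, diffusion time,
#'   polynomial order).
#' @param D embedding dimension.
#' @param interval interpolation interval.
#' @param edge_drop_rate,feature_mask_rate augmentation rates.
#' @param tau,epochs,learning_rate training settings.
#' @param n_seeds seeds for the repeated-run protocol (default 8).
#' @param asw_on silhouette convention, `"pred"` or `"truth"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = "synthetic", labels_path = NULL,
                       synthetic = synthetic_spec(),
                       h = 0.15, correlation = "pearson",
                       family = "heat", variant = "interpolated",
                       alpha = 0.9, t = 2, K = 6L, D = 64L,
                       interval = c(-0.9, 0.9),
                       edge_drop_rate = 0.2, feature_mask_rate = 0.2,
                       tau = 0.5, epochs = 100L, learning_rate = 1e-3,
                       n_seeds = 8L, asw_on = "pred") {
  compat <- list(
    rwr = c("truncated", "interpolated"),
    heat = c("taylor", "interpolated"),
    beta = "direct",
    none = c("random", "adjacency-gcn")
  )
  family <- match.arg(family, names(compat))
  variant <- match.arg(variant,
                       c("truncated", "taylor", "interpolated", "direct",
                         "random", "adjacency-gcn"))
  if (!variant %in% compat[[family]]) {
    rlang::abort(sprintf("variant '%s' is incompatible with family '%s'",
                         variant, family))
  }
  cfg <- structure(
    list(input = input, labels_path = labels_path, synthetic = synthetic,
         h = h, correlation = correlation, family = family, variant = variant,
         alpha = alpha, t = t, K = as.integer(K), D = as.integer(D),
         interval = interval, edge_drop_rate = edge_drop_rate,
         feature_mask_rate = feature_mask_rate, tau = tau,
         epochs = as.integer(epochs), learning_rate = learning_rate,
         n_seeds = as.integer(n_seeds), asw_on = asw_on),
    class = "run_config"
  )
  cfg
}

init_scheme_of <- function(cfg) {
  switch(paste(cfg$family, cfg$variant, sep = "/"),
    "rwr/truncated" = "rwr_truncated",
    "rwr/interpolated" = "rwr_interpolated",
    "heat/taylor" = "heat_taylor",
    "heat/interpolated" = "heat_interpolated",
    "beta/direct" = "beta_direct",
    "none/random" = "random",
    "none/adjacency-gcn" = "adjacency-gcn"
  )
}

#' Read/write a run configuration as YAML
#'
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- if (!is.null(y$synthetic)) do.call(synthetic_spec, y$synthetic)
         else synthetic_spec()
  y$synthetic <- syn
  do.call(run_config, y)
}

#' @rdname read_run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  y <- unclass(cfg)
  y$synthetic <- unclass(y$synthetic)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the full clustering pipeline
#'
#' Synthesize or load the corpus, build the correlation-threshold similarity
#' graph, train contrastive embeddings with the configured filter
#' initialization once per seed, cluster (K-means at the true type count
#' when labels exist, plus Louvain on the embedding kNN graph), and
#' evaluate. All artifacts — embeddings, predicted labels, per-seed metrics,
#' coefficient dumps, training logs and a manifest — are written under
#' `out_dir`.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @param seeds integer seeds; defaults to `1:n_seeds` from the config.
#' @return Invisibly, a list with `metrics` (a `metrics_report`), `fits`
#'   (per-seed `gcl_fit`s), `graph`, `truth`, and `out_dir`.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir = NULL, seeds = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  seeds <- seeds %||% seq_len(cfg$n_seeds)
  data <- load_pipeline_input(cfg)
  graph <- build_similarity_graph(
    data$expression,
    graph_build_config(h = cfg$h, correlation = cfg$correlation)
  )
  # shared feature preparation for every method (encoder and PCA baselines):
  # impute, then z-score each protein
  feats <- standardize_proteins(impute_missing(data$expression)$values)
  enc <- encoder_config(K = cfg$K, D = cfg$D, interval = cfg$interval,
                        init = if (cfg$variant == "adjacency-gcn")
                          "heat_interpolated" else init_scheme_of(cfg),
                        alpha = cfg$alpha, t = cfg$t)
  aug <- augmentation_config(cfg$edge_drop_rate, cfg$feature_mask_rate)
  truth <- data$truth
  k_true <- if (!is.null(truth)) length(unique(truth$label)) else NULL

  fits <- list()
  per_seed <- purrr::map_dfr(seeds, function(s) {
    fit <- train_gcl(
      feats, graph, enc, aug,
      train_config(epochs = cfg$epochs, learning_rate = cfg$learning_rate,
                   tau = cfg$tau, seed = s),
      model = if (cfg$variant == "adjacency-gcn") "adjacency-gcn" else "spectral"
    )
    fits[[as.character(s)]] <<- fit
    H <- fit$embedding
    pred_km <- if (!is.null(k_true)) kmeans_cluster(H, k_true, seed = s)
               else louvain_cluster_embedding(H, seed = s)
    pred_lv <- louvain_cluster_embedding(H, seed = s)
    final_loss <- if (nrow(fit$log)) fit$log$loss[nrow(fit$log)] else NA_real_
    row <- tibble::tibble(final_loss = final_loss)
    if (!is.null(truth)) {
      ev <- evaluate_clustering(H, truth$label, pred_km, asw_on = cfg$asw_on)
      row <- dplyr::bind_cols(ev, row)
      row$ari_louvain <- ari(truth$label, pred_lv)
    } else {
      row$asw <- asw(H, pred_lv)
      row$n_clusters <- pred_lv$n_clusters
    }
    dplyr::mutate(row, seed = s, .before = 1L)
  })
  metrics <- metrics_report(per_seed)

  if (!is.null(out_dir)) {
    write_pipeline_outputs(cfg, out_dir, data, graph, fits, metrics, seeds)
  }
  invisible(list(metrics = metrics, fits = fits, graph = graph,
                 truth = truth, out_dir = out_dir))
}

load_pipeline_input <- function(cfg) {
  if (identical(cfg$input, "synthetic")) {
    generate_corpus(cfg$synthetic)
  } else {
    expr <- read_expression(cfg$input)
    truth <- NULL
    if (!is.null(cfg$labels_path)) {
      lab <- utils::read.table(cfg$labels_path, header = TRUE, sep = "\t")
      idx <- match(expr$cell_ids, lab[[1L]])
      if (anyNA(idx)) rlang::abort("labels file does not cover all cells")
      truth <- tibble::tibble(cell_id = expr$cell_ids,
                              label = as.integer(as.factor(lab[[2L]][idx])))
    }
    list(expression = expr, truth = truth)
  }
}

write_pipeline_outputs <- function(cfg, out_dir, data, graph, fits, metrics,
                                   seeds) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_edge_list(graph, p("graph_edges.txt"))
  write_metrics_report(metrics, p("metrics.tsv"))
  for (s in names(fits)) {
    fit <- fits[[s]]
    H <- fit$embedding
    emb <- data.frame(cell_id = data$expression$cell_ids, H)
    utils::write.table(emb, p(sprintf("embedding_seed%s.tsv", s)), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(fit$log, p(sprintf("train_log_seed%s.tsv", s)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(data$truth)) {
    utils::write.table(data$truth, p("labels.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  first <- fits[[1L]]
  if (first$model == "spectral") {
    dump <- tibble::tibble(
      order = seq_along(first$init_coeffs$coeffs) - 1L,
      initial = first$init_coeffs$coeffs,
      learned = first$state$c
    )
    utils::write.table(dump, p("coefficients.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  manifest <- list(
    config_hash = rlang::hash(unclass(cfg)),
    seeds = seeds,
    n_cells = n_cells(data$expression),
    n_proteins = n_proteins(data$expression),
    n_edges = n_edges(graph),
    package_version = as.character(utils::packageVersion("scspectral")),
    r_version = R.version.string
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}

#' Parameter sweep over pipeline configurations
#'
#' Runs the pipeline once per (grid point, seed) and returns a long tibble —
#' the data behind parameter-sensitivity panels (filter parameter grids,
#' graph-threshold sweeps).
#'
#' @param base a [run_config()] supplying every field not being swept.
#' @param grid data frame (or named list, crossed) whose columns are
#'   `run_config` fields to vary, e.g. `list(t = 1:5)` or `list(h = c(0.05,
#'   0.15, 0.3, 0.5, 0.75))`.
#' @param seeds integer seeds per grid point (default `1:n_seeds`).
#' @return A tibble with one row per (grid point, seed): the grid columns,
#'   `seed`, `n_edges`, and every metric column.
#' @export
sweep_grid <- function(base = run_config(), grid, seeds = NULL) {
  if (!is.data.frame(grid)) grid <- expand.grid(grid, stringsAsFactors = FALSE)
  grid <- tibble::as_tibble(grid)
  seeds <- seeds %||% seq_len(base$n_seeds)
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    cfg <- base
    for (nm in names(grid)) cfg[[nm]] <- grid[[nm]][[i]]
    res <- tryCatch(
      run_pipeline(cfg, out_dir = NULL, seeds = seeds),
      error = function(e) {
        rlang::warn(sprintf("grid point %d failed: %s", i, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(res)) return(tibble::tibble())
    dplyr::bind_cols(
      grid[rep(i, nrow(res$metrics$per_seed)), , drop = FALSE],
      dplyr::mutate(res$metrics$per_seed, n_edges = n_edges(res$graph))
    )
  })
}
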