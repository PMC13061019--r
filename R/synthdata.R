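#' Specification of a synthetic single-cell proteomics corpus
#'
#' Describes a corpus with planted cell types, per-type marker-protein
#' programs, Gaussian measurement noise in log-abundance space, uniform
#' (missing-at-random) dropout, and optional additive protein-wise batch
#' shifts. Defaults describe a three-type, 180-cell, 300-protein corpus with
#' moderate noise and dropout, sized so a full contrastive-training benchmark
#' runs in minutes on one CPU.
#'
#' @param n_types number of planted cell types.
#' @param cells_per_type cells per type; a single value or one per type.
#' @param n_proteins number of proteins.
#' @param n_marker_proteins_per_type markers elevated in each type; marker
#'   sets are disjoint across types, so
#'   `n_types * n_marker_proteins_per_type <= n_proteins` is required.
#' @param effect_size additive mean shift of marker proteins, in natural-log
#'   abundance units (2 is roughly a 7-fold elevation).
#' @param noise_sd sd of i.i.d. Gaussian measurement noise (log units).
#' @param dropout_rate probability that any entry is missing.
#' @param cell_shift_sd sd of a per-cell log-depth offset added to every
#'   protein of a cell, emulating cell-to-cell acquisition-depth variation
#'   (sample loading / total ion current). Pearson correlation between cell
#'   profiles is invariant to this offset, which is precisely why
#'   correlation-threshold graphs are the field's similarity of choice;
#'   Euclidean methods are not invariant to it.
#' @param n_batches number of batches; cells are assigned round-robin within
#'   type so batches are balanced.
#' @param batch_shift_sd sd of the additive protein-wise batch shift
#'   (log units); ignored when `n_batches == 1`.
#' @param baseline_sd sd of the per-protein baseline log-abundance drawn once
#'   per protein (protein-to-protein spread of the proteome).
#' @param seed integer seed; the corpus is bit-identical for identical
#'   spec + seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_types = 3L,
                           cells_per_type = 60L,
                           n_proteins = 300L,
                           n_marker_proteins_per_type = 25L,
                           effect_size = 1.5,
                           noise_sd = 1.2,
                           dropout_rate = 0.35,
                           cell_shift_sd = 1,
                           n_batches = 1L,
                           batch_shift_sd = 0.3,
                           baseline_sd = 1,
                           seed = 1L) {
  stop_if_not_scalar_number(n_types, "n_types", lo = 1, integer = TRUE)
  if (!is.numeric(cells_per_type) ||
      !(length(cells_per_type) %in% c(1L, n_types)) ||
      any(cells_per_type < 1) || any(cells_per_type != round(cells_per_type))) {
    rlang::abort("`cells_per_type` must be positive integer(s), one or one per type")
  }
  stop_if_not_scalar_number(n_proteins, "n_proteins", lo = 1, integer = TRUE)
  stop_if_not_scalar_number(n_marker_proteins_per_type,
                            "n_marker_proteins_per_type", lo = 1, integer = TRUE)
  stop_if_not_scalar_number(effect_size, "effect_size", lo = 0)
  stop_if_not_scalar_number(noise_sd, "noise_sd", lo = 0)
  stop_if_not_scalar_number(dropout_rate, "dropout_rate", lo = 0, hi = 1)
  stop_if_not_scalar_number(cell_shift_sd, "cell_shift_sd", lo = 0)
  stop_if_not_scalar_number(n_batches, "n_batches", lo = 1, integer = TRUE)
  stop_if_not_scalar_number(batch_shift_sd, "batch_shift_sd", lo = 0)
  stop_if_not_scalar_number(baseline_sd, "baseline_sd", lo = 0)
  if (n_types * n_marker_proteins_per_type > n_proteins) {
    rlang::abort("marker sets exceed the proteome: n_types * markers > n_proteins")
  }
  structure(
    list(
      n_types = as.integer(n_types),
      cells_per_type = as.integer(rep_len(cells_per_type, n_types)),
      n_proteins = as.integer(n_proteins),
      n_marker_proteins_per_type = as.integer(n_marker_proteins_per_type),
      effect_size = effect_size,
      noise_sd = noise_sd,
      dropout_rate = dropout_rate,
      cell_shift_sd = cell_shift_sd,
      n_batches = as.integer(n_batches),
      batch_shift_sd = batch_shift_sd,
      baseline_sd = baseline_sd,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic corpus with planted cell types
#'
#' Log-abundance model: each protein p draws a baseline once,
#' `mu_p ~ N(base, baseline_sd^2)`; a cell of type t adds `effect_size` on
#' that type's marker proteins, its batch adds a protein-wise shift
#' `N(0, batch_shift_sd^2)`, every protein of a cell shares the cell's
#' acquisition-depth offset `N(0, cell_shift_sd^2)`, and i.i.d.
#' `N(0, noise_sd^2)` measurement noise is added. Each entry is then dropped (set missing) independently with
#' probability `dropout_rate`.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `expression` (an `expr_matrix`) and `truth`, a tibble
#'   with columns `cell_id`, `label` (integer cell type, 1..n_types) and
#'   `batch`.
#' @export
generate_corpus <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- sum(spec$cells_per_type)
    d <- spec$n_proteins
    labels <- rep(seq_len(spec$n_types), times = spec$cells_per_type)
    # balanced batch assignment: round-robin within each type
    batch <- unlist(lapply(spec$cells_per_type, function(m) {
      rep_len(seq_len(spec$n_batches), m)
    }), use.names = FALSE)

    baseline <- 5 + spec$baseline_sd * stats::rnorm(d)
    y <- matrix(baseline, nrow = n, ncol = d, byrow = TRUE)

    m <- spec$n_marker_proteins_per_type
    for (t in seq_len(spec$n_types)) {
      markers <- ((t - 1L) * m + 1L):(t * m)
      y[labels == t, markers] <- y[labels == t, markers] + spec$effect_size
    }
    if (spec$n_batches > 1L && spec$batch_shift_sd > 0) {
      shift <- matrix(stats::rnorm(spec$n_batches * d, sd = spec$batch_shift_sd),
                      nrow = spec$n_batches)
      y <- y + shift[batch, , drop = FALSE]
    }
    if (spec$cell_shift_sd > 0) {
      y <- y + stats::rnorm(n, sd = spec$cell_shift_sd)
    }
    if (spec$noise_sd > 0) {
      y <- y + matrix(stats::rnorm(n * d, sd = spec$noise_sd), nrow = n)
    }
    if (spec$dropout_rate > 0) {
      drop <- matrix(stats::runif(n * d) < spec$dropout_rate, nrow = n)
      y[drop] <- NA_real_
    }
    cell_ids <- sprintf("cell_%03d", seq_len(n))
    list(
      expression = expression_matrix(
        y, cell_ids = cell_ids,
        protein_ids = sprintf("prot_%04d", seq_len(d))
      ),
      truth = tibble::tibble(
        cell_id = cell_ids,
        label = as.integer(labels),
        batch = as.integer(batch)
      )
    )
  })
}

#' Marker indices of each planted type
#'
#' @param spec a [synthetic_spec()].
#' @return list of integer vectors, one per type.
#' @export
marker_proteins <- function(spec) {
  m <- spec$n_marker_proteins_per_type
  lapply(seq_len(spec$n_types), function(t) ((t - 1L) * m + 1L):(t * m))
}

#' Type-separation diagnostic of a corpus
#'
#' Mean within-type minus mean between-type Pearson correlation of cell
#' profiles (pairwise-complete observations). Larger is better separated;
#' used to check that separation grows with the planted effect size.
#'
#' @param expression an `expr_matrix`.
#' @param labels integer vector of cell types.
#' @return a single number.
#' @export
type_separation <- function(expression, labels) {
  cc <- suppressWarnings(
    stats::cor(t(expression$values), use = "pairwise.complete.obs")
  )
  cc[!is.finite(cc)] <- 0
  same <- outer(labels, labels, "==")
  diag(same) <- NA
  ut <- upper.tri(cc)
  mean(cc[ut & !is.na(same) & same]) - mean(cc[ut & !is.na(same) & !same])
}
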