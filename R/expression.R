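#' Cell-by-protein expression matrix
#'
#' Container for a cells x proteins abundance matrix. Missing quantifications
#' (dropout, a dominant feature of single-cell mass-spectrometry data) are
#' encoded as `NA`; the observation mask is derived, never stored separately.
#'
#' @param values numeric matrix, cells in rows, proteins in columns; `NA`
#'   marks a missing quantification.
#' @param cell_ids,protein_ids character identifiers; defaults are generated
#'   when the matrix carries no dimnames.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, cell_ids = NULL, protein_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    rlang::abort("`values` must be a numeric matrix")
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    rlang::abort("expression matrix needs at least one cell and one protein")
  }
  cell_ids <- cell_ids %||% rownames(values) %||%
    sprintf("cell_%d", seq_len(nrow(values)))
  protein_ids <- protein_ids %||% colnames(values) %||%
    sprintf("protein_%d", seq_len(ncol(values)))
  if (length(cell_ids) != nrow(values)) {
    rlang::abort("`cell_ids` length must equal the number of rows")
  }
  if (length(protein_ids) != ncol(values)) {
    rlang::abort("`protein_ids` length must equal the number of columns")
  }
  dimnames(values) <- NULL
  structure(
    list(
      values = values,
      cell_ids = as.character(cell_ids),
      protein_ids = as.character(protein_ids)
    ),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d cells x %d proteins (%.1f%% missing)\n",
    n_cells(x), n_proteins(x), 100 * mean(is.na(x$values))
  ))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x an `expr_matrix`.
#' @export
n_cells <- function(x) nrow(x$values)

#' @rdname expression_matrix
#' @export
n_proteins <- function(x) ncol(x$values)

#' Observation mask
#'
#' @param x an `expr_matrix`.
#' @return logical matrix, `TRUE` where the entry was observed.
#' @export
observed_mask <- function(x) !is.na(x$values)

#' Fill in missing abundances
#'
#' Replaces missing entries so the matrix can serve as node-feature input to
#' the graph encoder (the graph itself is built mask-aware and does not need
#' imputation). `protein_median` uses the per-protein median of observed
#' values; a protein with no observed value at all falls back to the global
#' median (reported via a message).
#'
#' @param x an `expr_matrix`.
#' @param strategy `"protein_median"` (default) or `"zero"`.
#' @return An `expr_matrix` with no missing entries; observed entries are
#'   unchanged.
#' @export
impute_missing <- function(x, strategy = c("protein_median", "zero")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  if (!anyNA(v)) {
    return(x)
  }
  if (strategy == "zero") {
    v[is.na(v)] <- 0
  } else {
    med <- apply(v, 2L, stats::median, na.rm = TRUE)
    all_missing <- is.na(med)
    if (any(all_missing)) {
      med[all_missing] <- stats::median(v, na.rm = TRUE)
      rlang::inform(sprintf(
        "%d protein(s) fully missing; imputed with the global median",
        sum(all_missing)
      ))
    }
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- med[idx[, 2L]]
  }
  expression_matrix(v, x$cell_ids, x$protein_ids)
}

#' Z-score each protein over its observed entries
#'
#' Per-protein standardization (constant proteins are left at 0), the shared
#' feature preparation for the encoder and the classical baselines. Accepts
#' and returns a plain matrix; `NA`s are ignored in the moments and retained
#' in the output.
#'
#' @param values numeric matrix, cells in rows.
#' @return numeric matrix of the same shape.
#' @export
standardize_proteins <- function(values) {
  mu <- colMeans(values, na.rm = TRUE)
  sdev <- apply(values, 2L, stats::sd, na.rm = TRUE)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  sweep(sweep(values, 2L, mu, "-"), 2L, sdev, "/")
}
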