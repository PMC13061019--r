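#' Read and write expression matrices
#'
#' Dense form: delimited text, header row of protein IDs, first column cell
#' IDs, empty fields or `NA` for missing quantifications. Sparse form:
#' Matrix Market coordinate (`.mtx`), where stored entries are the observed
#' ones; optional sidecar files `<stem>.cells.txt` / `<stem>.proteins.txt`
#' carry the identifiers (one per line).
#'
#' @param path file to read or write; format is taken from the extension
#'   (`.tsv`/`.txt` tab, `.csv` comma, `.mtx` Matrix Market) unless `format`
#'   is given.
#' @param format `"auto"`, `"tsv"`, `"csv"` or `"mtx"`.
#' @return `read_expression()` returns an `expr_matrix`.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "csv", "mtx")) {
  format <- resolve_format(path, match.arg(format))
  if (format == "mtx") {
    sm <- methods::as(Matrix::readMM(path), "TsparseMatrix")
    # stored entries of the sparse file are the observed quantifications
    # (explicit zeros included); everything unstored is missing
    v <- matrix(NA_real_, nrow(sm), ncol(sm))
    v[cbind(sm@i + 1L, sm@j + 1L)] <- sm@x
    stem <- sub("\\.mtx$", "", path)
    cids <- sidecar_ids(paste0(stem, ".cells.txt"), nrow(sm), "cell")
    pids <- sidecar_ids(paste0(stem, ".proteins.txt"), ncol(sm), "protein")
    return(expression_matrix(v, cids, pids))
  }
  sep <- if (format == "csv") "," else "\t"
  lines <- readLines(path)
  if (length(lines) < 2L) rlang::abort(sprintf("'%s': no data rows", path))
  fields <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths != widths[1L])) {
    bad <- which(widths != widths[1L])[1L]
    rlang::abort(sprintf(
      "'%s': ragged row at line %d (%d fields, expected %d)",
      path, bad, widths[bad], widths[1L]
    ))
  }
  protein_ids <- fields[[1L]][-1L]
  body <- fields[-1L]
  cell_ids <- vapply(body, `[[`, character(1L), 1L)
  v <- t(vapply(body, function(f) {
    suppressWarnings(as.numeric(f[-1L]))
  }, numeric(length(protein_ids))))
  if (length(protein_ids) == 1L) v <- matrix(v, ncol = 1L)
  expression_matrix(v, cell_ids, protein_ids)
}

#' @rdname read_expression
#' @param x an `expr_matrix`.
#' @export
write_expression <- function(x, path, format = c("auto", "tsv", "csv", "mtx")) {
  stopifnot(inherits(x, "expr_matrix"))
  format <- resolve_format(path, match.arg(format))
  if (format == "mtx") {
    v <- x$values
    obs <- which(!is.na(v), arr.ind = TRUE)
    sm <- Matrix::sparseMatrix(i = obs[, 1L], j = obs[, 2L],
                               x = v[obs], dims = dim(v))
    Matrix::writeMM(sm, path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(x$cell_ids, paste0(stem, ".cells.txt"))
    writeLines(x$protein_ids, paste0(stem, ".proteins.txt"))
    return(invisible(path))
  }
  sep <- if (format == "csv") "," else "\t"
  v <- x$values
  dimnames(v) <- list(x$cell_ids, x$protein_ids)
  df <- data.frame(cell_id = x$cell_ids, v, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

resolve_format <- function(path, format) {
  if (format != "auto") return(format)
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
    csv = "csv",
    mtx = "mtx",
    tsv = ,
    txt = "tsv",
    rlang::abort(sprintf("cannot infer format from '%s'; pass `format`", path))
  )
}

sidecar_ids <- function(path, n, what) {
  if (file.exists(path)) {
    ids <- readLines(path)
    if (length(ids) != n) {
      rlang::abort(sprintf("'%s': %d ids for %d %ss", path, length(ids), n, what))
    }
    ids
  } else {
    sprintf("%s_%d", what, seq_len(n))
  }
}

#' Read and write edge lists
#'
#' Two-column whitespace-delimited cell identifiers, one edge per line,
#' preceded by a `#nodes N` header comment; an optional `#id i name` block
#' maps identifiers to node order. Files written by [write_edge_list()]
#' always carry that block.
#'
#' @param path file path.
#' @return [read_edge_list()] returns a `cell_graph`.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  header <- grep("^#nodes\\s+\\d+", lines, value = TRUE)
  if (length(header) == 0L) {
    rlang::abort(sprintf("'%s': missing '#nodes N' header", path))
  }
  n <- as.integer(sub("^#nodes\\s+(\\d+).*", "\\1", header[1L]))
  id_lines <- grep("^#id\\s", lines, value = TRUE)
  ids <- NULL
  if (length(id_lines)) {
    parts <- strsplit(sub("^#id\\s+", "", id_lines), "\\s+")
    ids <- character(n)
    for (p in parts) ids[as.integer(p[[1L]])] <- p[[2L]]
  }
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(body) == 0L) {
    return(cell_graph(n, cell_ids = ids))
  }
  parts <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    line_no <- which(lines == body[bad[1L]])[1L]
    rlang::abort(sprintf("'%s': malformed edge at line %d", path, line_no))
  }
  ends <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
  if (is.null(ids)) {
    idx <- suppressWarnings(matrix(as.integer(ends), ncol = 2L))
    if (anyNA(idx)) {
      rlang::abort(sprintf("'%s': non-numeric endpoints but no '#id' block", path))
    }
  } else {
    idx <- matrix(match(ends, ids), ncol = 2L)
    if (anyNA(idx)) rlang::abort(sprintf("'%s': edge names an unknown cell id", path))
  }
  cell_graph(n, edges = idx, cell_ids = ids)
}

#' @rdname read_edge_list
#' @param g a `cell_graph`.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "cell_graph"))
  ids <- g$cell_ids %||% sprintf("v%d", seq_len(g$n_nodes))
  lines <- c(
    sprintf("#nodes %d", g$n_nodes),
    sprintf("#id %d %s", seq_len(g$n_nodes), ids)
  )
  if (n_edges(g) > 0L) {
    lines <- c(lines, paste(ids[g$edges[, 1L]], ids[g$edges[, 2L]]))
  }
  writeLines(lines, path)
  invisible(path)
}
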