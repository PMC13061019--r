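test_that("edges follow the inclusive correlation threshold", {
  x <- expression_matrix(rbind(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  g <- build_similarity_graph(x, graph_build_config(h = 0.5, standardize = FALSE))
  expect_equal(n_edges(g), 1L)  # identical profiles: corr = 1 >= 0.5

  y <- expression_matrix(rbind(c(1, 2, 3, 4), c(4, 3, 2, 1)))
  g2 <- build_similarity_graph(y, graph_build_config(h = 0.15, standardize = FALSE))
  expect_equal(n_edges(g2), 0L)  # exact anti-correlation: -1 < 0.15
})

test_that("toy 3-cell graph matches hand-computed correlations", {
  x <- toy_expression()
  r_ab <- pearson_by_hand(x$values[1, ], x$values[2, ])
  r_ac <- pearson_by_hand(x$values[1, ], x$values[3, ])
  r_bc <- pearson_by_hand(x$values[2, ], x$values[3, ])
  expect_gt(r_ab, 0.15)
  expect_lt(r_ac, 0.15)
  expect_lt(r_bc, 0.15)
  g <- build_similarity_graph(x, graph_build_config(h = 0.15, standardize = FALSE))
  expect_equal(g$edges, matrix(c(1L, 2L), 1))
  # package correlations agree with the explicit formula
  cc <- suppressWarnings(stats::cor(t(x$values)))
  expect_equal(cc[1, 2], r_ab, tolerance = 1e-12)
})

test_that("undefined correlations become isolated with a warning", {
  x <- expression_matrix(rbind(c(1, 2, 3), c(5, 5, 5), c(1, 2, 4)))
  expect_warning(
    g <- build_similarity_graph(x, graph_build_config(h = 0.1, standardize = FALSE)),
    "undefined correlation"
  )
  # constant cell 2 is treated as correlation 0 < h, so it joins nothing;
  # cells 1 and 3 correlate strongly
  expect_true(all(g$edges != 2L))
  expect_equal(n_edges(g), 1L)
})

test_that("normalized adjacency matches hand computation and stays in [-1, 1]", {
  single <- normalize_adjacency(cell_graph(1L))
  expect_equal(as_dense(single), matrix(1))

  pair <- normalize_adjacency(cell_graph(2L, matrix(c(1L, 2L), 1)))
  dm <- as_dense(pair)
  expect_equal(dm, matrix(0.5, 2, 2))
  expect_equal(sort(eigen(dm, symmetric = TRUE)$values), c(0, 1))

  for (seed in 1:3) {
    inst <- random_instance(40, 3, p_edge = 0.1, seed = seed)
    m <- as_dense(normalize_adjacency(inst$graph))
    expect_equal(m, t(m))
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1 - 1e-10 & ev <= 1 + 1e-10))
    # isolated nodes keep a unit self-loop
    iso <- setdiff(seq_len(40), unique(as.vector(inst$graph$edges)))
    if (length(iso)) expect_equal(unname(diag(m)[iso]), rep(1, length(iso)))
  }
})

test_that("edge count is non-increasing in the threshold h", {
  corp <- default_corpus()
  counts <- vapply(c(0.05, 0.15, 0.3, 0.5, 0.75), function(h) {
    n_edges(build_similarity_graph(corp$expression, graph_build_config(h = h)))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], counts[5])
})

test_that("expression IO round-trips across formats", {
  x <- expression_matrix(rbind(c(1.5, NA, 3), c(NA, 2.25, -1)),
                         cell_ids = c("c1", "c2"),
                         protein_ids = c("pA", "pB", "pC"))
  for (ext in c("tsv", "csv", "mtx")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_expression(x, path)
    y <- read_expression(path)
    expect_equal(y$values, x$values)
    expect_equal(y$cell_ids, x$cell_ids)
    expect_equal(y$protein_ids, x$protein_ids)
  }
})

test_that("the packaged toy fixture survives a write/read cycle", {
  f <- system.file("extdata", "toy_expression.tsv", package = "scspectral")
  x <- read_expression(f)
  expect_equal(dim(x$values), c(4L, 5L))
  expect_equal(sum(is.na(x$values)), 3L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(x, path)
  expect_equal(read_expression(path), x)
})

test_that("mtx stored-entry count equals observed entries", {
  x <- expression_matrix(rbind(c(1, NA, 2), c(NA, NA, 3)))
  path <- withr::local_tempfile(fileext = ".mtx")
  write_expression(x, path)
  lines <- readLines(path)
  size_line <- lines[!startsWith(lines, "%")][1L]  # "nrow ncol nnz"
  expect_equal(strsplit(size_line, "\\s+")[[1L]][3L], "3")
  expect_equal(sum(!is.na(read_expression(path)$values)), 3L)
})

test_that("ragged rows are rejected with a line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cell_id\tp1\tp2", "c1\t1\t2", "c2\t9"), path)
  expect_error(read_expression(path), "line 3")
})

test_that("edge lists round-trip and tolerate emptiness", {
  g <- cell_graph(4L, rbind(c(1, 3), c(2, 4)), cell_ids = letters[1:4])
  path <- withr::local_tempfile(fileext = ".txt")
  write_edge_list(g, path)
  h <- read_edge_list(path)
  expect_equal(h$edges, g$edges)
  expect_equal(h$cell_ids, g$cell_ids)

  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines("#nodes 5", empty)
  e <- read_edge_list(empty)
  expect_equal(e$n_nodes, 5L)
  expect_equal(n_edges(e), 0L)
})

test_that("cell_graph canonicalizes and validates edges", {
  g <- cell_graph(3L, rbind(c(3, 1), c(1, 3), c(2, 3)))
  expect_equal(g$edges, rbind(c(1L, 3L), c(2L, 3L)))
  expect_error(cell_graph(3L, rbind(c(1, 1))), "self-loops")
  expect_error(cell_graph(3L, rbind(c(0, 2))), "endpoints")
})
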