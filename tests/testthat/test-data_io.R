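test_that("edge-list ingestion expands undirected rows, dedups and drops self-loops", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\tdirected",
               "A\tB\t1",
               "B\tC\t0",
               "A\tB\t1",
               "D\tD\t1"), f)
  expect_message(g <- read_prior_edgelist(f), "self-loop")
  key <- paste(g$nodes[g$edges$from], g$nodes[g$edges$to], sep = ">")
  expect_setequal(key, c("A>B", "B>C", "C>B"))
  # D only appeared in a self-loop row; it still enters the node universe
  expect_true(all(c("A", "B", "C") %in% g$nodes))
})

test_that("edge-list ingestion is order-independent and validates input", {
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  rows <- c("A\tB\t1", "B\tC\t0", "C\tA\t1")
  writeLines(c("source\ttarget\tdirected", rows), f1)
  writeLines(c("source\ttarget\tdirected", rev(rows)), f2)
  g1 <- read_prior_edgelist(f1)
  g2 <- read_prior_edgelist(f2)
  key <- function(g) sort(paste(g$nodes[g$edges$from], g$nodes[g$edges$to]))
  expect_identical(key(g1), key(g2))

  fe <- withr::local_tempfile(fileext = ".tsv")
  writeLines("source\ttarget", fe)
  expect_error(read_prior_edgelist(fe), "empty")
  fb <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget", "A\tB", "\tC"), fb)
  expect_error(read_prior_edgelist(fb), "line")
})

test_that("restriction to expressed genes induces the right subgraph", {
  g <- gene_graph(c("A", "B", "C"), from = c(1, 2), to = c(2, 3))
  expr <- lineage_expression(matrix(1, 2, 3), cells = c("c1", "c2"),
                             genes = c("B", "C", "D"))
  sub <- restrict_to_expressed(g, expr)
  expect_identical(sub$nodes, c("B", "C"))   # expr order, graph universe
  expect_identical(sub$edges$from, 1L)
  expect_identical(sub$edges$to, 2L)

  same <- restrict_to_expressed(
    g, lineage_expression(matrix(1, 2, 3), cells = c("c1", "c2"),
                          genes = c("C", "A", "B")))
  expect_setequal(same$nodes, g$nodes)
  expect_equal(nrow(same$edges), 2L)

  none <- lineage_expression(matrix(1, 2, 1), cells = c("c1", "c2"),
                             genes = "Z")
  expect_error(restrict_to_expressed(g, none), "shared")
})

test_that("co-expression augmentation adds top correlated pairs bidirectionally", {
  set.seed(11)
  n <- 20
  x <- matrix(rnorm(30 * n), 30, n)
  x[, 2] <- x[, 1]                      # perfect rank correlation pair
  x <- abs(x)
  genes <- sprintf("g%02d", 1:n)
  expr <- lineage_expression(x, cells = sprintf("c%02d", 1:30), genes = genes)
  g <- gene_graph(genes, from = c(1, 3), to = c(3, 5))
  # oracle: Spearman by rank formula for the planted pair
  rho <- cor(rank(x[, 1]), rank(x[, 2]))
  expect_equal(rho, 1)
  aug <- augment_with_coexpression(g, expr, top_frac = 1 / 190, rho_min = 0.6)
  key <- paste(aug$nodes[aug$edges$from], aug$nodes[aug$edges$to])
  expect_true(all(c("g01 g02", "g02 g01") %in% key))
  expect_setequal(aug$edges$origin[match(c("g01 g02", "g02 g01"), key)],
                  "coexpression")
  # prior edges survive untouched
  expect_true(all(c("g01 g03", "g03 g05") %in% key))

  # idempotent on re-application
  aug2 <- augment_with_coexpression(aug, expr, top_frac = 1 / 190,
                                    rho_min = 0.6)
  expect_identical(aug$edges[order(aug$edges$from, aug$edges$to), ],
                   aug2$edges[order(aug2$edges$from, aug2$edges$to), ])
})

test_that("co-expression augmentation respects the rho threshold and prior origins", {
  set.seed(12)
  x <- abs(matrix(rnorm(40 * 10), 40, 10))     # independent noise
  genes <- sprintf("g%02d", 1:10)
  expr <- lineage_expression(x, cells = sprintf("c%02d", 1:40), genes = genes)
  g <- gene_graph(genes, from = 1, to = 2)
  aug <- augment_with_coexpression(g, expr, top_frac = 0.5, rho_min = 0.99)
  expect_equal(nrow(aug$edges), 1L)            # nothing clears the bar

  # a pair that is both a prior edge and co-expressed stays `prior`
  x2 <- x; x2[, 2] <- x2[, 1]
  expr2 <- lineage_expression(x2, cells = sprintf("c%02d", 1:40),
                              genes = genes)
  g2 <- gene_graph(genes, from = c(1, 2), to = c(2, 1))
  aug2 <- augment_with_coexpression(g2, expr2, top_frac = 1 / 45,
                                    rho_min = 0.6)
  expect_equal(nrow(aug2$edges), 2L)
  expect_setequal(aug2$edges$origin, "prior")

  # constant gene: correlations dropped with a message
  x3 <- x; x3[, 4] <- 1
  expr3 <- lineage_expression(x3, cells = sprintf("c%02d", 1:40),
                              genes = genes)
  expect_message(augment_with_coexpression(g, expr3, top_frac = 0.5),
                 "constant")
})

test_that("expression formats round-trip and agree across formats", {
  set.seed(3)
  vals <- matrix(round(runif(20), 6), 5, 4)
  expr <- lineage_expression(vals, cells = paste0("c", 1:5),
                             genes = paste0("g", 1:4))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_expression(expr, tsv)
  back <- read_expression(tsv)
  expect_equal(back$values, expr$values)
  expect_identical(back$cells, expr$cells)
  expect_identical(back$genes, expr$genes)

  dir <- withr::local_tempdir()
  mtx <- file.path(dir, "m.mtx")
  Matrix::writeMM(Matrix::Matrix(vals, sparse = TRUE), mtx)
  writeLines(expr$genes, file.path(dir, "genes.txt"))
  writeLines(expr$cells, file.path(dir, "cells.txt"))
  frommtx <- read_expression(mtx)
  expect_equal(frommtx$values, expr$values)

  # all-zero sparse matrix reads as an all-zero dense matrix
  zero <- file.path(dir, "z.mtx")
  Matrix::writeMM(Matrix::sparseMatrix(i = integer(), j = integer(),
                                       dims = c(5, 4), x = numeric()), zero)
  dir.create(file.path(dir, "zz"))
  file.copy(zero, file.path(dir, "zz", "z.mtx"))
  writeLines(expr$genes, file.path(dir, "zz", "genes.txt"))
  writeLines(expr$cells, file.path(dir, "zz", "cells.txt"))
  expect_true(all(read_expression(file.path(dir, "zz", "z.mtx"))$values == 0))

  # shape mismatch between matrix and sidecars is a hard error
  writeLines(expr$genes[-1], file.path(dir, "genes.txt"))
  expect_error(read_expression(mtx), "match")
})

test_that("GRN TSV round-trips the edge set exactly", {
  g <- gene_graph(c("A", "B", "C"), from = c(1, 2, 3), to = c(2, 3, 1))
  grn <- structure(list(nodes = g$nodes,
                        edges = data.frame(source = c("A", "B", "C"),
                                           target = c("B", "C", "A"),
                                           weight = c(1.5, 0.25, 3),
                                           origin = "prior",
                                           stringsAsFactors = FALSE),
                        k_d = 8L), class = "lineage_grn")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_grn(grn, f)
  back <- read_grn(f)
  expect_identical(back$edges$source, grn$edges$source)
  expect_identical(back$edges$target, grn$edges$target)
  expect_equal(back$edges$weight, grn$edges$weight)
})

test_that("pseudotime attaches by cell id and missing cells are an error", {
  expr <- lineage_expression(matrix(1, 3, 2), cells = c("a", "b", "c"),
                             genes = c("g1", "g2"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cell_id\tpseudotime", "b\t0.5", "a\t0.1", "c\t0.9"), f)
  expr2 <- read_expression({
    tsv <- withr::local_tempfile(fileext = ".tsv")
    write_expression(expr, tsv); tsv
  }, pseudotime_path = f)
  expect_equal(expr2$pseudotime, c(0.1, 0.5, 0.9))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cell_id\tpseudotime", "a\t0.1"), f2)
  expect_error(attach_pseudotime <- fatedrivers:::attach_pseudotime(
    expr, read_pseudotime(f2)), "missing")
})
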