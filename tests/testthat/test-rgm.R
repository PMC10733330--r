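rgm_fixture <- function(n_members = 15, sig = TRUE, anticorr = integer()) {
  set.seed(61)
  n <- n_members + 2
  genes <- c("REG", sprintf("m%02d", seq_len(n_members)), "OTHER")
  m <- 30
  rx <- runif(m, 0, 3)
  vals <- matrix(runif(m * n, 0, 1), m, n)
  vals[, 1] <- rx
  for (j in seq_len(n_members)) {
    vals[, j + 1] <- if (j %in% anticorr) max(rx) - rx + runif(m, 0, 0.01)
    else rx + runif(m, 0, 0.01)
  }
  expr <- lineage_expression(vals, cells = sprintf("c%02d", 1:m),
                             genes = genes)
  grn <- structure(list(
    nodes = genes,
    edges = data.frame(source = "REG",
                       target = genes[2:(n_members + 1)],
                       weight = 1, origin = "prior",
                       from = 1L, to = 2:(n_members + 1),
                       beta_in = 1, beta_out = 1,
                       stringsAsFactors = FALSE),
    k_d = 8L), class = "lineage_grn")
  de <- structure(list(genes = genes,
                       l = rep(1, n),
                       significant = c(TRUE, rep(sig, n_members), FALSE),
                       k_states = 2L), class = "diffexp_profile")
  list(expr = expr, grn = grn, de = de)
}

test_that("module extraction respects the size filter and member signs", {
  fx <- rgm_fixture(n_members = 15, anticorr = c(3, 7))
  mods <- extract_rgms(fx$grn, "REG", fx$de, fx$expr)
  expect_length(mods, 1L)                     # out-module only (no preds)
  mod <- mods[[1]]
  expect_identical(mod$kind, "out_degree")
  expect_equal(mod$size, 15L)
  expect_true(all(mod$members %in% fx$grn$edges$target))
  expect_identical(unname(mod$signs[c("m03", "m07")]),
                   c("repressed", "repressed"))
  expect_true(all(mod$signs[setdiff(names(mod$signs),
                                    c("m03", "m07"))] == "activated"))

  # nine significant successors: below the size floor, nothing emitted
  fx9 <- rgm_fixture(n_members = 9)
  expect_length(extract_rgms(fx9$grn, "REG", fx9$de, fx9$expr), 0L)

  # members must be significantly differentially expressed
  fxn <- rgm_fixture(n_members = 15, sig = FALSE)
  expect_length(extract_rgms(fxn$grn, "REG", fxn$de, fxn$expr), 0L)
})

test_that("in-degree modules collect predecessors", {
  fx <- rgm_fixture(n_members = 12)
  # reverse the edges: the 12 genes now regulate REG
  grn <- fx$grn
  grn$edges <- data.frame(source = grn$edges$target, target = "REG",
                          weight = 1, origin = "prior",
                          from = grn$edges$to, to = 1L,
                          beta_in = 1, beta_out = 1,
                          stringsAsFactors = FALSE)
  mods <- extract_rgms(grn, "REG", fx$de, fx$expr)
  expect_length(mods, 1L)
  expect_identical(mods[[1]]$kind, "in_degree")
  expect_equal(mods[[1]]$size, 12L)
})

test_that("activity is 1 for a module filling the top ranks and 0 off the top", {
  n <- 100
  genes <- sprintf("g%03d", 1:n)
  vals <- matrix(rep(seq(n, 1) / n, 2), 2, n, byrow = TRUE)
  expr <- lineage_expression(vals, cells = c("c1", "c2"), genes = genes)
  mod_top <- structure(list(regulator = "x", kind = "out_degree",
                            members = genes[1:4],
                            signs = rep("activated", 4), size = 4L),
                       class = "regulon_module")
  mod_bottom <- structure(list(regulator = "x", kind = "out_degree",
                               members = genes[51:60],
                               signs = rep("activated", 10), size = 10L),
                          class = "regulon_module")
  act <- aucell_activity(expr, list(top = mod_top, bottom = mod_bottom),
                         top_frac = 0.05)
  expect_equal(unname(act[, "top"]), c(1, 1))
  expect_equal(unname(act[, "bottom"]), c(0, 0))
  expect_true(all(act >= 0 & act <= 1))
})

test_that("activity is rank-based, hence invariant to monotone transforms", {
  set.seed(62)
  n <- 200; m <- 15
  genes <- sprintf("g%03d", 1:n)
  vals <- matrix(runif(m * n, 0, 4), m, n)
  expr <- lineage_expression(vals, cells = sprintf("c%02d", 1:m),
                             genes = genes)
  mod <- structure(list(regulator = "x", kind = "out_degree",
                        members = sample(genes, 25),
                        signs = rep("activated", 25), size = 25L),
                   class = "regulon_module")
  a1 <- aucell_activity(expr, list(m = mod), seed = 4)
  expr2 <- lineage_expression(log1p(vals^2 * 3), cells = expr$cells,
                              genes = genes)
  a2 <- aucell_activity(expr2, list(m = mod), seed = 4)
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("mean activity of a random module matches the analytic expectation", {
  # uniform random ranks: E[cumulative hits at rank r] = r * m / N, so
  # E[area] = (m / N) * T (T + 1) / 2 with T top ranks, normalized by
  # sum over r of min(r, m)
  set.seed(63)
  n <- 1000; m_mod <- 50; top_frac <- 0.05; cells <- 400
  t_top <- ceiling(top_frac * n)
  genes <- sprintf("g%04d", 1:n)
  vals <- matrix(runif(cells * n), cells, n)
  expr <- lineage_expression(vals, cells = sprintf("c%03d", 1:cells),
                             genes = genes)
  mod <- structure(list(regulator = "x", kind = "out_degree",
                        members = genes[1:m_mod],
                        signs = rep("activated", m_mod), size = m_mod),
                   class = "regulon_module")
  act <- aucell_activity(expr, list(m = mod))
  expected <- (m_mod / n) * t_top * (t_top + 1) / 2 /
    sum(pmin(seq_len(t_top), m_mod))
  se <- sd(act[, 1]) / sqrt(cells)
  expect_lt(abs(mean(act[, 1]) - expected), 4 * se + 1e-3)
})

test_that("a pseudotime-restricted program scores early cells above late cells", {
  fix <- tiny_trained_fixture()
  sc <- fix$scenario
  # the early program: T01 and its targets are high only at small pseudotime
  mod <- structure(list(regulator = "T01", kind = "out_degree",
                        members = c("T02", "T03", "T04", "T05"),
                        signs = rep("activated", 4), size = 4L),
                   class = "regulon_module")
  act <- aucell_activity(sc$expression, list(early = mod), top_frac = 0.4)
  lab <- bin_pseudotime(sc$expression, 2)$state_labels
  expect_gt(mean(act[lab == 1, 1]), mean(act[lab == 2, 1]))
})

test_that("modules serialize to GMT-style lines", {
  fx <- rgm_fixture(n_members = 12, anticorr = 2)
  mods <- extract_rgms(fx$grn, "REG", fx$de, fx$expr)
  f <- withr::local_tempfile(fileext = ".gmt")
  write_rgms(mods, f)
  line <- strsplit(readLines(f)[1], "\t")[[1]]
  expect_identical(line[1], names(mods)[1])
  expect_identical(line[2], "out_degree")
  expect_true("m02-" %in% line)
})
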