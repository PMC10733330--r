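test_that("differential-expression scaling is a monotone sigmoid", {
  l <- c(0, 0.5, 1, 4)
  expect_equal(de_scalar(l, 0, 0), rep(0.5, 4))
  expect_equal(de_scalar(0, 1, 0), 0.5)
  d <- de_scalar(l, 2, -1)
  expect_true(all(diff(d) > 0))
  expect_true(all(d > 0 & d < 1))
})

test_that("cosine attention scores the canonical geometries", {
  expect_equal(attention_score(c(1, 0), c(0, 1), 0.7), 0)
  expect_equal(attention_score(c(1, 2), c(1, 2), 1), 1)
  expect_equal(attention_score(c(1, 2), -c(1, 2), 0.8), 0.8)  # |cos| = 1
  expect_equal(attention_score(c(0, 0), c(1, 1), 1), 0)       # zero norm
  # scale invariance of the cosine
  expect_equal(attention_score(5 * c(1, 3), c(2, 1), 0.6),
               attention_score(c(1, 3), c(2, 1), 0.6))
})

test_that("temperature softmax normalizes and sharpens as specified", {
  expect_equal(normalize_attention(rep(0.3, 4), 0.25), rep(0.25, 4))
  a <- normalize_attention(c(1, 0), 0.25)
  expect_equal(a, c(exp(4) / (exp(4) + 1), 1 / (exp(4) + 1)))
  set.seed(1)
  for (i in 1:20) {
    out <- normalize_attention(runif(sample(2:8, 1), -2, 2),
                               tau = runif(1, 0.05, 1))
    expect_equal(sum(out), 1, tolerance = 1e-12)
    expect_true(all(out >= 0))
  }
})

test_that("feature corruption shuffles rows only, deterministically per seed", {
  x <- matrix(1:20, 5, 4)
  c1 <- corrupt_features(x, seed = 9)
  c2 <- corrupt_features(x, seed = 9)
  expect_identical(c1, c2)
  # multiset of rows preserved
  expect_setequal(apply(c1, 1, paste, collapse = ","),
                  apply(x, 1, paste, collapse = ","))
})

test_that("contrastive loss hits its analytic anchors", {
  # discriminator exactly at 0.5 everywhere: loss = ln 2
  h <- diag(2); m <- matrix(0, 2, 2); s <- c(0.5, 0.5)
  expect_equal(dgi_loss(h, h, s, m), log(2))
  # near-perfect discrimination: loss near 0
  m2 <- diag(2) * 50
  expect_lt(dgi_loss(diag(2), -diag(2), c(1, 1), m2), 1e-10)
  set.seed(4)
  for (i in 1:10) {
    hr <- matrix(rnorm(8), 4); hc <- matrix(rnorm(8), 4)
    expect_gte(dgi_loss(hr, hc, rnorm(2), matrix(rnorm(4), 2)), 0)
  }
})

test_that("training is reproducible, reduces the loss and keeps softmax rows normalized", {
  fix <- tiny_trained_fixture()
  enc <- fix$encoder
  expect_lt(tail(enc$losses, 1), enc$losses[1])
  expect_lt(check_attention_sums(enc$attention, tol = 1e-6), 1e-6)
  expect_true(all(is.finite(enc$embeddings)))
  expect_identical(rownames(enc$embeddings), fix$scenario$prior$nodes)
  expect_true(all(enc$de_encoding$D > 0 & enc$de_encoding$D < 1))

  enc2 <- train_encoder(fix$scenario$prior, fix$expr, fix$de,
                        enc$config)
  for (l in 1:2) for (dir in c("in", "out")) {
    expect_lt(max(abs(enc$attention$alpha[[l]][[dir]] -
                      enc2$attention$alpha[[l]][[dir]])), 1e-6)
  }
  expect_equal(enc$embeddings, enc2$embeddings, tolerance = 1e-12)
})

test_that("the forward pass is equivariant under gene relabeling", {
  ns <- getNamespace("fatedrivers")
  set.seed(31)
  g <- gene_graph(paste0("g", 1:6), from = c(1, 2, 3, 5, 6),
                  to = c(2, 3, 4, 4, 5))
  x <- matrix(rnorm(6 * 10), 6, 10)
  l <- runif(6)
  cfg <- encoder_config(hidden_dim = 4, out_dim = 4, heads = 2, seed = 2)
  params <- ns$encoder_init_params(cfg, 10)
  fwd <- function(graph, feats, lv) {
    tape <- ns$ad_tape()
    pn <- lapply(params, function(p) ns$ad_param(tape, p))
    ns$encoder_forward(tape, pn, ns$ad_const(tape, feats),
                       ns$encoder_pairs(graph), cfg, lv)$h$value
  }
  perm <- c(4, 2, 6, 1, 3, 5)             # new position of each old node
  inv <- order(perm)
  gp <- gene_graph(g$nodes[inv], from = perm[g$edges$from],
                   to = perm[g$edges$to])
  out <- fwd(g, x, l)
  out_p <- fwd(gp, x[inv, ], l[inv])
  expect_equal(out_p, out[inv, ], tolerance = 1e-10)
})

test_that("an isolated gene attends only to itself", {
  fix <- tiny_trained_fixture()
  g <- fix$scenario$prior
  iso <- gene_graph(c(g$nodes, "LONE"),
                    from = g$edges$from, to = g$edges$to)
  expr <- fix$expr
  vals <- cbind(expr$values, LONE = runif(nrow(expr$values)))
  expr2 <- lineage_expression(vals, cells = expr$cells,
                              genes = c(expr$genes, "LONE"),
                              pseudotime = expr$pseudotime)
  expr2$state_labels <- expr$state_labels
  enc <- train_encoder(iso, expr2, NULL,
                       encoder_config(hidden_dim = 8, out_dim = 4,
                                      heads = 2, epochs = 3, seed = 1))
  for (l in 1:2) for (dir in c("in", "out")) {
    a <- enc$attention$alpha[[l]][[dir]]
    pr <- enc$attention$pairs[[dir]]
    self_rows <- which(pr$ci == 13 & pr$ni == 13)
    expect_equal(unname(a[self_rows, ]), rep(1, ncol(a)), tolerance = 1e-12)
  }
})

test_that("disabling the DE encoding freezes the scaling at a constant", {
  fix <- tiny_trained_fixture()
  enc <- train_encoder(fix$scenario$prior, fix$expr, fix$de,
                       encoder_config(hidden_dim = 8, out_dim = 4, heads = 2,
                                      epochs = 3, seed = 1,
                                      use_de_encoding = FALSE))
  expect_true(all(enc$de_encoding$D == 0.5))
})
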