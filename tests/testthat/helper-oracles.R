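# Independent oracles and shared fixtures for the test suite.

# random digraph as a gene_graph, edge probability p, no self-loops
random_digraph <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(stats::runif(n * n) < p, n, n)
  diag(a) <- FALSE
  idx <- which(a, arr.ind = TRUE)
  gene_graph(sprintf("n%02d", seq_len(n)),
             from = idx[, 1L], to = idx[, 2L])
}

# --- exhaustive-search oracles (independent of the package's solvers) ------

oracle_is_acyclic <- function(n, succ, removed = integer()) {
  alive <- rep(TRUE, n)
  alive[removed] <- FALSE
  indeg <- integer(n)
  for (v in seq_len(n)) {
    if (!alive[v]) next
    for (w in succ[[v]]) {
      if (w == v) return(FALSE)
      if (alive[w]) indeg[w] <- indeg[w] + 1L
    }
  }
  stack <- which(alive & indeg == 0L)
  cnt <- 0L
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    cnt <- cnt + 1L
    for (w in succ[[v]]) {
      if (!alive[w]) next
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) stack <- c(stack, w)
    }
  }
  cnt == sum(alive)
}

graph_succ <- function(graph) {
  n <- length(graph$nodes)
  lapply(seq_len(n), function(v) graph$edges$to[graph$edges$from == v])
}

# minimum FVS size (and one witness) by subset enumeration, smallest first
oracle_mfvs <- function(graph) {
  n <- length(graph$nodes)
  succ <- graph_succ(graph)
  for (k in 0:n) {
    for (s in combn_list(n, k)) {
      if (oracle_is_acyclic(n, succ, removed = s))
        return(list(size = k, set = s))
    }
  }
  stop("unreachable")
}

# minimum dominating set size under successor-domination semantics
oracle_mds <- function(graph) {
  n <- length(graph$nodes)
  succ <- lapply(seq_len(n), function(v)
    graph$edges$to[graph$edges$from == v])
  for (k in 0:n) {
    for (s in combn_list(n, k)) {
      covered <- unique(c(s, unlist(succ[s])))
      if (length(covered) == n) return(list(size = k, set = s))
    }
  }
  stop("unreachable")
}

combn_list <- function(n, k) {
  if (k == 0L) return(list(integer()))
  apply(utils::combn(n, k), 2L, identity, simplify = FALSE)
}

# --- shared trained fixture -------------------------------------------------
# The default-scenario training is expensive; acceptance tests that inspect
# different aspects of the same trained model share one run.

.fixture_cache <- new.env(parent = emptyenv())

default_trained_fixture <- function() {
  if (!is.null(.fixture_cache$default)) return(.fixture_cache$default)
  sc <- make_scenario(seed = 101L)
  graph <- restrict_to_expressed(sc$prior, sc$expression)
  graph <- augment_with_coexpression(graph, sc$expression)
  expr <- bin_pseudotime(sc$expression, sc$k_states)
  de <- compute_logfc(expr)
  enc <- train_encoder(graph, expr, de,
                       encoder_config(seed = 101L))   # full 350 epochs
  .fixture_cache$default <- list(scenario = sc, graph = graph, expr = expr,
                                 de = de, encoder = enc)
  .fixture_cache$default
}

# small trained model on the 12-gene worked example, shared by unit tests
tiny_trained_fixture <- function(epochs = 80L) {
  key <- paste0("tiny", epochs)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  sc <- tiny_worked_example()
  expr <- bin_pseudotime(sc$expression, 2L)
  de <- compute_logfc(expr)
  enc <- train_encoder(sc$prior, expr, de,
                       encoder_config(hidden_dim = 16L, out_dim = 8L,
                                      heads = 2L, epochs = epochs,
                                      seed = 5L))
  .fixture_cache[[key]] <- list(scenario = sc, expr = expr, de = de,
                                encoder = enc)
  .fixture_cache[[key]]
}

# minimum number of candidate sets covering the reduced MDS instance
oracle_cover_size <- function(rd) {
  sets <- rd$candidates
  need <- rd$uncovered
  for (k in 0:length(sets)) {
    for (s in combn_list(length(sets), k)) {
      if (all(need %in% unlist(sets[s]))) return(k)
    }
  }
  stop("reduced instance is infeasible")
}
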