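#' Construct a directed gene-interaction graph
#'
#' A `gene_graph` holds an ordered set of unique gene symbols and a set of
#' directed edges between them.  It is the substrate both for the attention
#' encoder (which normalizes attention over graph neighborhoods) and for the
#' network-control solvers.  Self-loops are excluded; self-attention is
#' handled separately inside the encoder.
#'
#' @param nodes character vector of unique, non-empty gene symbols.
#' @param from,to integer vectors indexing `nodes`; edge k is
#'   `from[k] -> to[k]`.
#' @param origin character vector, per-edge provenance tag
#'   (`"prior"` or `"coexpression"`).
#' @return An object of class `gene_graph` with elements `nodes`,
#'   `edges` (data.frame with integer columns `from`, `to` and character
#'   `origin`).
#' @export
gene_graph <- function(nodes, from = integer(), to = integer(),
                       origin = rep("prior", length(from))) {
  nodes <- as.character(nodes)
  stopifnot(length(from) == length(to), length(origin) == length(from))
  if (anyDuplicated(nodes)) stop("gene symbols must be unique")
  if (any(!nzchar(nodes))) stop("gene symbols must be non-empty")
  from <- as.integer(from); to <- as.integer(to)
  n <- length(nodes)
  if (length(from) && (min(c(from, to)) < 1L || max(c(from, to)) > n))
    stop("edge endpoint out of range")
  if (any(from == to)) stop("self-loops are not allowed in a gene_graph")
  key <- paste(from, to)
  if (anyDuplicated(key)) {
    keep <- !duplicated(key)
    from <- from[keep]; to <- to[keep]; origin <- origin[keep]
  }
  structure(list(
    nodes = nodes,
    edges = data.frame(from = from, to = to, origin = as.character(origin),
                       stringsAsFactors = FALSE)
  ), class = "gene_graph")
}

#' @export
print.gene_graph <- function(x, ...) {
  cat(sprintf("gene_graph: %d genes, %d directed edges (%d prior, %d coexpression)\n",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$origin == "prior"),
              sum(x$edges$origin == "coexpression")))
  invisible(x)
}

n_genes <- function(graph) length(graph$nodes)

#' Adjacency matrix of a gene graph
#'
#' @param graph a [gene_graph()].
#' @return sparse logical adjacency `A` with `A[i, j] = 1` iff edge `i -> j`.
#' @export
adjacency <- function(graph) {
  Matrix::sparseMatrix(i = graph$edges$from, j = graph$edges$to, x = 1,
                       dims = c(n_genes(graph), n_genes(graph)),
                       dimnames = list(graph$nodes, graph$nodes))
}

in_degree <- function(graph) {
  tabulate(graph$edges$to, nbins = n_genes(graph))
}

out_degree <- function(graph) {
  tabulate(graph$edges$from, nbins = n_genes(graph))
}

#' Read a prior gene-interaction network from an edge-list file
#'
#' Reads a delimited text file with columns `source`, `target` and an
#' optional direction flag.  Undirected rows (flag `0`) are expanded into
#' both directions, matching the convention of prior interaction databases
#' that mix regulatory (directed) and physical (undirected) links.
#' Duplicate edges are collapsed and self-loop rows are dropped with a
#' message.
#'
#' @param path path to a TSV/CSV file with a header row.
#' @param directedness_column name of the optional 0/1 direction column;
#'   if `NULL` (default) the third column is used when present, otherwise
#'   all rows are treated as directed.
#' @param sep field separator; `"\t"` by default.
#' @return a [gene_graph()] whose node set is the union of all symbols seen.
#' @export
read_prior_edgelist <- function(path, directedness_column = NULL, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (nrow(tab) == 0L) stop("edge list is empty: ", path)
  if (ncol(tab) < 2L) stop("edge list needs at least two columns: ", path)
  src <- trimws(as.character(tab[[1L]]))
  tgt <- trimws(as.character(tab[[2L]]))
  bad <- which(!nzchar(src) | !nzchar(tgt) | is.na(src) | is.na(tgt))
  if (length(bad))
    stop("unparsable edge row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "))
  if (!is.null(directedness_column)) {
    if (!directedness_column %in% names(tab))
      stop("direction column not found: ", directedness_column)
    directed <- as.integer(tab[[directedness_column]]) != 0L
  } else if (ncol(tab) >= 3L) {
    directed <- as.integer(tab[[3L]]) != 0L
  } else {
    directed <- rep(TRUE, length(src))
  }
  directed[is.na(directed)] <- TRUE
  self <- src == tgt
  if (any(self)) {
    message(sum(self), " self-loop row(s) dropped")
    src <- src[!self]; tgt <- tgt[!self]; directed <- directed[!self]
  }
  if (!length(src)) stop("no usable edges in ", path)
  # undirected rows appear in both orientations
  s2 <- c(src, tgt[!directed])
  t2 <- c(tgt, src[!directed])
  nodes <- sort(unique(c(s2, t2)))
  gene_graph(nodes,
             from = match(s2, nodes),
             to = match(t2, nodes))
}

#' Restrict a graph to genes present in an expression matrix
#'
#' Returns the induced subgraph on the intersection of the graph's genes
#' and the expression gene set; node order follows the expression object so
#' that node features align with matrix columns.
#'
#' @param graph a [gene_graph()].
#' @param expr a [lineage_expression()].
#' @return a [gene_graph()] on the shared genes.
#' @export
restrict_to_expressed <- function(graph, expr) {
  shared <- expr$genes[expr$genes %in% graph$nodes]
  if (!length(shared)) stop("no genes shared between graph and expression")
  idx <- match(graph$nodes, shared)          # old index -> new index
  keep <- !is.na(idx[graph$edges$from]) & !is.na(idx[graph$edges$to])
  gene_graph(shared,
             from = idx[graph$edges$from[keep]],
             to = idx[graph$edges$to[keep]],
             origin = graph$edges$origin[keep])
}

#' Augment a prior graph with strong co-expression pairs
#'
#' Adds, as bidirectional `coexpression` edges, the top fraction of gene
#' pairs ranked by absolute Spearman correlation among pairs whose
#' correlation exceeds `rho_min`.  The denominator of the top fraction is
#' the number of unordered gene pairs over the graph's node set.  Prior
#' edges are never removed or re-tagged; a pair already present keeps its
#' `prior` origin.  Genes with constant expression are excluded from the
#' ranking.
#'
#' @param graph a [gene_graph()] (typically after [restrict_to_expressed()]).
#' @param expr a [lineage_expression()] covering the graph's genes.
#' @param top_frac fraction of all unordered pairs to add (default 0.01).
#' @param rho_min minimum Spearman rho (default 0.6).
#' @return the augmented [gene_graph()].
#' @export
augment_with_coexpression <- function(graph, expr, top_frac = 0.01,
                                      rho_min = 0.6) {
  if (nrow(expr$values) < 3L) stop("need at least 3 cells for co-expression")
  cols <- match(graph$nodes, expr$genes)
  if (anyNA(cols)) stop("graph contains genes absent from expression")
  x <- expr$values[, cols, drop = FALSE]
  sds <- apply(x, 2L, stats::sd)
  const <- sds == 0
  if (any(const))
    message(sum(const), " constant-expression gene(s) excluded from co-expression")
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  rho[is.na(rho)] <- 0
  rho[const, ] <- 0; rho[, const] <- 0
  n <- n_genes(graph)
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  vals <- rho[ut]
  cand <- which(vals > rho_min)
  n_top <- floor(top_frac * n * (n - 1) / 2)
  if (length(cand) && n_top > 0L) {
    av <- abs(vals[cand])
    if (length(cand) > n_top) {
      cutoff <- sort(av, decreasing = TRUE)[n_top]
      cand <- cand[av >= cutoff]           # ties at the cutoff all kept
    }
    i <- ut[cand, 1L]; j <- ut[cand, 2L]
    newf <- c(i, j); newt <- c(j, i)
    key_old <- paste(graph$edges$from, graph$edges$to)
    key_new <- paste(newf, newt)
    fresh <- !(key_new %in% key_old)
    if (any(fresh)) {
      graph <- gene_graph(
        graph$nodes,
        from = c(graph$edges$from, newf[fresh]),
        to = c(graph$edges$to, newt[fresh]),
        origin = c(graph$edges$origin, rep("coexpression", sum(fresh))))
    }
  }
  graph
}
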