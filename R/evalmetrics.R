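#' Area under the precision-recall curve for an edge ranking
#'
#' Scores a weighted edge prediction against a ground-truth edge set.  The
#' candidate universe is every ordered gene pair (minus self-pairs) over the
#' genes shared by prediction and truth; pairs absent from the prediction
#' are scored 0.  The area is computed by step integration (average
#' precision over the true positives), which handles heavily unbalanced
#' truth sets better than ROC-style summaries.
#'
#' @param ranking data frame with columns `source`, `target`, `weight`.
#' @param truth data frame with columns `source`, `target` (directed true
#'   edges).
#' @return scalar in `[0, 1]`.
#' @export
auprc <- function(ranking, truth) {
  u <- eval_universe(ranking, truth)
  if (!length(u$labels)) stop("no true edges inside the shared gene universe")
  ord <- order(-u$scores, u$keys)
  lab <- u$labels[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  sum(prec[lab]) / sum(lab)
}

#' Early precision ratio
#'
#' Precision among the top-k ranked pairs, where k is the number of true
#' edges in the shared universe, divided by the truth density; a random
#' ranking scores about 1, a perfect one `1 / density`.
#'
#' @inheritParams auprc
#' @return non-negative scalar.
#' @export
epr <- function(ranking, truth) {
  u <- eval_universe(ranking, truth)
  k <- sum(u$labels)
  if (k == 0L) stop("no true edges inside the shared gene universe")
  ord <- order(-u$scores, u$keys)
  early_prec <- sum(u$labels[ord][seq_len(k)]) / k
  density <- k / length(u$labels)
  early_prec / density
}

# shared candidate universe: ordered pairs over common genes, no self-pairs
eval_universe <- function(ranking, truth) {
  genes <- intersect(unique(c(ranking$source, ranking$target)),
                     unique(c(truth$source, truth$target)))
  if (length(genes) < 2L) stop("fewer than 2 shared genes")
  pairs <- expand.grid(source = genes, target = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  keys <- paste(pairs$source, pairs$target, sep = "\r")
  rk <- paste(ranking$source, ranking$target, sep = "\r")
  scores <- rep(0, length(keys))
  hit <- match(keys, rk)
  scores[!is.na(hit)] <- ranking$weight[hit[!is.na(hit)]]
  tk <- unique(paste(truth$source, truth$target, sep = "\r"))
  list(scores = scores, labels = keys %in% tk, keys = keys)
}

#' Topology diagnostics of a network
#'
#' Reports node and edge counts, the slope and R-squared of a least-squares
#' fit of `log10 P(k)` on `log10 k` over the total-degree distribution, and
#' the average clustering coefficient of the undirected projection.
#' Scale-free-like networks show a negative slope with a good fit; networks
#' with fewer than 3 distinct positive degrees get `NaN` slope.
#'
#' @param grn a `lineage_grn` or [gene_graph()].
#' @return named list: `n_nodes`, `n_edges`, `slope`, `r_squared`,
#'   `clustering`.
#' @export
topology_report <- function(grn) {
  nodes <- grn$nodes
  ed <- grn$edges
  from <- if (!is.null(ed$from)) ed$from else match(ed$source, nodes)
  to <- if (!is.null(ed$to)) ed$to else match(ed$target, nodes)
  if (length(nodes) < 10L) stop("topology report needs at least 10 nodes")
  deg <- tabulate(from, length(nodes)) + tabulate(to, length(nodes))
  tab <- table(deg[deg > 0])
  k <- as.numeric(names(tab))
  pk <- as.numeric(tab) / sum(tab)
  if (length(k) < 3L) {
    slope <- NaN; r2 <- NaN
  } else {
    fit <- stats::lm(log10(pk) ~ log10(k))
    slope <- unname(stats::coef(fit)[2L])
    r2 <- summary(fit)$r.squared
  }
  ig <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  ig <- igraph::add_vertices(ig, max(0L, length(nodes) - igraph::vcount(ig)))
  und <- igraph::as_undirected(ig, mode = "collapse")
  clustering <- igraph::transitivity(und, type = "localaverage", isolates = "zero")
  list(n_nodes = length(nodes), n_edges = length(from),
       slope = slope, r_squared = r2, clustering = clustering)
}
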