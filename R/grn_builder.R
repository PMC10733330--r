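#' Degree-scaled attention weights for prior edges
#'
#' Softmax attention coefficients are only comparable within one
#' neighborhood; multiplying each coefficient by the degree of its central
#' node (in-degree in the in-coming channel, out-degree in the out-going
#' channel) makes them globally comparable, and the per-edge weight is the
#' average of the two channels.  Heads are averaged before scaling.  Self
#' pairs take part in the softmax but are never emitted as edges.
#'
#' @param att an `attention_record` from [train_encoder()].
#' @param graph the [gene_graph()] the encoder ran on (degrees are taken
#'   from it).
#' @return object of class `edge_weight_table`: `edges` (source, target,
#'   origin and index columns) and `layers`, a list of two data frames with
#'   columns `beta_in`, `beta_out`, `beta`.
#' @export
scale_attention <- function(att, graph) {
  stopifnot(inherits(att, "attention_record"))
  ne <- nrow(graph$edges)
  if (att$n_edges != ne || !identical(att$nodes, graph$nodes))
    stop("attention record does not match graph")
  indeg <- in_degree(graph); outdeg <- out_degree(graph)
  from <- graph$edges$from; to <- graph$edges$to
  layers <- lapply(1:2, function(l) {
    a_in <- rowMeans(att$alpha[[l]][["in"]])[seq_len(ne)]
    a_out <- rowMeans(att$alpha[[l]][["out"]])[seq_len(ne)]
    beta_in <- a_in * indeg[to]          # center of the in-channel: target
    beta_out <- a_out * outdeg[from]     # center of the out-channel: source
    data.frame(beta_in = beta_in, beta_out = beta_out,
               beta = (beta_in + beta_out) / 2)
  })
  structure(list(
    edges = data.frame(source = graph$nodes[from], target = graph$nodes[to],
                       from = from, to = to, origin = graph$edges$origin,
                       stringsAsFactors = FALSE),
    layers = layers),
    class = "edge_weight_table")
}

#' Combine per-layer edge weights
#'
#' Blends the scaled attention weights of the two encoder layers:
#' `mu * layer1 + (1 - mu) * layer2`, applied channel-wise.
#'
#' @param t1,t2 the per-layer weight data frames
#'   (`edge_weight_table$layers`).
#' @param mu mixing weight in `[0, 1]` (default 0.5).
#' @return data frame with `beta_in`, `beta_out`, `beta_combined`.
#' @export
combine_layers <- function(t1, t2, mu = 0.5) {
  stopifnot(mu >= 0, mu <= 1, nrow(t1) == nrow(t2))
  data.frame(beta_in = mu * t1$beta_in + (1 - mu) * t2$beta_in,
             beta_out = mu * t1$beta_out + (1 - mu) * t2$beta_out,
             beta_combined = mu * t1$beta + (1 - mu) * t2$beta)
}

#' Select the cell-lineage-specific GRN
#'
#' Ranks prior edges by their combined weight and keeps the top
#' `min(k_d * N, |edges|)`, where `k_d` is the target average degree.  Ties
#' at the cutoff are broken by (source, target) symbol order so that the
#' selection is deterministic.
#'
#' @param weights an `edge_weight_table` whose layers have been combined, or
#'   a list with `edges` and a `combined` data frame (see
#'   [combine_layers()]); alternatively pass `combined` explicitly.
#' @param graph the [gene_graph()] defining the gene universe.
#' @param k_d target average degree (default 8).
#' @param combined optional data frame from [combine_layers()]; if missing,
#'   layers are combined with `mu = 0.5`.
#' @return object of class `lineage_grn`: `nodes` (all genes), `edges`
#'   (source, target, weight, origin, from, to, beta_in, beta_out), `k_d`.
#' @export
select_edges <- function(weights, graph, k_d = 8L, combined = NULL) {
  stopifnot(k_d >= 1L)
  if (is.null(combined))
    combined <- combine_layers(weights$layers[[1L]], weights$layers[[2L]])
  ed <- weights$edges
  stopifnot(nrow(ed) == nrow(combined))
  n_keep <- min(as.integer(k_d) * length(graph$nodes), nrow(ed))
  ord <- order(-combined$beta_combined, ed$source, ed$target)
  keep <- ord[seq_len(n_keep)]
  structure(list(
    nodes = graph$nodes,
    edges = data.frame(source = ed$source[keep], target = ed$target[keep],
                       weight = combined$beta_combined[keep],
                       origin = ed$origin[keep],
                       from = ed$from[keep], to = ed$to[keep],
                       beta_in = combined$beta_in[keep],
                       beta_out = combined$beta_out[keep],
                       stringsAsFactors = FALSE),
    k_d = as.integer(k_d)),
    class = "lineage_grn")
}

#' @export
print.lineage_grn <- function(x, ...) {
  cat(sprintf("lineage_grn: %d genes, %d weighted edges (k_d = %s)\n",
              length(x$nodes), nrow(x$edges), x$k_d))
  invisible(x)
}
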