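#' Attention-derived influence scores
#'
#' A gene's importance in the lineage network is the log-transformed sum of
#' the degree-scaled attention weights over its GRN neighbors:
#' `S_in = ln(1 + sum over predecessors j of beta_out(j -> i))` and
#' `S_out = ln(1 + sum over successors j of beta_in(i -> j))`, combined as
#' `S = lambda * S_out + (1 - lambda) * S_in`.  The default `lambda = 0.8`
#' weights the outgoing side more, since influential regulators typically
#' have large out-degrees in a GRN.  Sums run over edges retained in the
#' lineage GRN only.
#'
#' @param grn a `lineage_grn` whose edges carry `beta_in` and `beta_out`
#'   channel weights (see [select_edges()]).
#' @param lam mixing weight in `[0, 1]`.
#' @return object of class `influence_scores`: data frame `scores` with
#'   columns `gene`, `S_in`, `S_out`, `S`, plus `lambda`.
#' @export
influence_scores <- function(grn, lam = 0.8) {
  stopifnot(lam >= 0, lam <= 1)
  nodes <- grn$nodes
  ed <- grn$edges
  from <- ed$from; to <- ed$to
  if (is.null(from)) { from <- match(ed$source, nodes); to <- match(ed$target, nodes) }
  sum_in <- rep(0, length(nodes))        # incoming beta_out, per target
  sum_out <- rep(0, length(nodes))       # outgoing beta_in, per source
  if (nrow(ed)) {
    acc <- rowsum(ed$beta_out, to)
    sum_in[as.integer(rownames(acc))] <- acc
    acc <- rowsum(ed$beta_in, from)
    sum_out[as.integer(rownames(acc))] <- acc
  }
  s_in <- log1p(sum_in); s_out <- log1p(sum_out)
  structure(list(
    scores = data.frame(gene = nodes, S_in = s_in, S_out = s_out,
                        S = lam * s_out + (1 - lam) * s_in,
                        stringsAsFactors = FALSE),
    lambda = lam),
    class = "influence_scores")
}

#' Select final driver regulators
#'
#' Intersects the `top_n` genes by influence score (ties broken by gene
#' symbol) with the control-derived candidate set, returning the overlap
#' ordered by descending score.
#'
#' @param scores an [influence_scores()] result.
#' @param candidates character vector of candidate genes
#'   (see [candidate_union()]).
#' @param top_n size of the influence shortlist (default 100).
#' @return character vector of driver regulators, best first.
#' @export
select_drivers <- function(scores, candidates, top_n = 100L) {
  tab <- scores$scores
  ord <- order(-tab$S, tab$gene)
  shortlist <- tab$gene[ord][seq_len(min(top_n, nrow(tab)))]
  drivers <- shortlist[shortlist %in% candidates]
  if (!length(drivers))
    warning("no candidate gene reached the influence shortlist")
  drivers
}

#' Network controllability metrics
#'
#' Summarizes how hard the network is to control: the controllability score
#' `1 - |D|/|V|` for each driver-gene set (higher means fewer drivers
#' suffice), the Jaccard index between the two sets (consistency of the two
#' control views), and the coverage of the final driver regulators among
#' all candidates.
#'
#' @param mfvs,mds character vectors: driver genes from the two methods.
#' @param drivers character vector of final driver regulators.
#' @param all_genes the gene universe of the network.
#' @return named list: `controllability_score_mfvs`,
#'   `controllability_score_mds`, `jaccard`, `coverage`.
#' @export
controllability_metrics <- function(mfvs, mds, drivers, all_genes) {
  stopifnot(all(mfvs %in% all_genes), all(mds %in% all_genes))
  nv <- length(all_genes)
  uni <- union(mfvs, mds)
  if (!length(uni)) {
    warning("empty candidate union; Jaccard and coverage undefined")
    jac <- NaN; cov <- NaN
  } else {
    jac <- length(intersect(mfvs, mds)) / length(uni)
    cov <- length(intersect(drivers, uni)) / length(uni)
  }
  list(controllability_score_mfvs = 1 - length(mfvs) / nv,
       controllability_score_mds = 1 - length(mds) / nv,
       jaccard = jac,
       coverage = cov)
}

#' Identify driver regulators of a lineage GRN
#'
#' Runs both network-control methods, ranks genes by influence score,
#' intersects the shortlist with the candidate union and reports
#' controllability metrics.
#'
#' @param grn a `lineage_grn` from [select_edges()].
#' @param lam influence mixing weight (default 0.8).
#' @param top_n influence shortlist size (default 100).
#' @param time_limit per-solver time budget in seconds.
#' @return object of class `driver_report`: `candidates_mfvs`,
#'   `candidates_mds`, `influence`, `scores` (per-gene table with
#'   `is_candidate` / `is_driver` flags), `drivers`, `metrics`, and the two
#'   `control_solution`s.
#' @export
identify_drivers <- function(grn, lam = 0.8, top_n = 100L, time_limit = 600) {
  mfvs <- solve_mfvs(grn, time_limit = time_limit)
  mds <- solve_mds(grn, time_limit = time_limit)
  cand <- candidate_union(mfvs, mds)
  infl <- influence_scores(grn, lam = lam)
  drivers <- select_drivers(infl, cand, top_n = top_n)
  tab <- infl$scores
  tab$is_candidate <- tab$gene %in% cand
  tab$is_driver <- tab$gene %in% drivers
  tab <- tab[order(-tab$S, tab$gene), ]
  rownames(tab) <- NULL
  metrics <- controllability_metrics(mfvs$driver_set, mds$driver_set,
                                     drivers, grn$nodes)
  structure(list(candidates_mfvs = mfvs$driver_set,
                 candidates_mds = mds$driver_set,
                 influence = infl, scores = tab, drivers = drivers,
                 metrics = metrics, mfvs = mfvs, mds = mds),
            class = "driver_report")
}

#' @export
print.driver_report <- function(x, ...) {
  cat(sprintf(paste0("driver_report: %d MFVS / %d MDS candidates, ",
                     "%d driver regulator(s)\n"),
              length(x$candidates_mfvs), length(x$candidates_mds),
              length(x$drivers)))
  cat(sprintf("  controllability: MFVS %.3f, MDS %.3f; Jaccard %.3f; coverage %.3f\n",
              x$metrics$controllability_score_mfvs,
              x$metrics$controllability_score_mds,
              x$metrics$jaccard, x$metrics$coverage))
  invisible(x)
}
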