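#' Extract regulon-like gene modules for driver regulators
#'
#' For each driver regulator, builds an out-degree module (its GRN
#' successors: the genes it regulates) and an in-degree module (its GRN
#' predecessors: its co-regulators).  Members are filtered to significantly
#' differentially expressed genes, and modules smaller than `min_size`
#' (default 10) are dropped.  Each member is signed by the Pearson
#' correlation of its expression with the regulator's across cells
#' (`activated` for non-negative, `repressed` for negative).
#'
#' @param grn a `lineage_grn`.
#' @param drivers character vector of driver regulators.
#' @param de a `diffexp_profile` from [compute_logfc()].
#' @param expr a [lineage_expression()] (for member signs).
#' @param min_size minimum module size (members, excluding the regulator).
#' @return list of `regulon_module` objects: `regulator`, `kind`
#'   (`out_degree` / `in_degree`), `members`, `signs`, `size`.
#' @export
extract_rgms <- function(grn, drivers, de, expr, min_size = 10L) {
  sig_genes <- de$genes[de$significant]
  modules <- list()
  for (reg in drivers) {
    for (kind in c("out_degree", "in_degree")) {
      members <- if (kind == "out_degree")
        grn$edges$target[grn$edges$source == reg]
      else
        grn$edges$source[grn$edges$target == reg]
      members <- sort(unique(setdiff(members, reg)))
      members <- members[members %in% sig_genes]
      if (length(members) < min_size) next
      rx <- expr$values[, reg]
      signs <- vapply(members, function(m) {
        mx <- expr$values[, m]
        if (stats::sd(mx) == 0 || stats::sd(rx) == 0) {
          message("zero-variance member ", m, "; sign set to activated")
          return("activated")
        }
        if (stats::cor(rx, mx) < 0) "repressed" else "activated"
      }, character(1))
      modules[[paste0(reg, if (kind == "out_degree") "(+)" else "(-)")]] <-
        structure(list(regulator = reg, kind = kind, members = members,
                       signs = signs, size = length(members)),
                  class = "regulon_module")
    }
  }
  modules
}

#' Per-cell module activity (area under the recovery curve)
#'
#' For each cell, genes are ranked by expression (descending; ties broken
#' by a seeded random jitter for determinism), and a module's activity is
#' the area under the recovery curve of its members within the top
#' `ceiling(top_frac * N)` ranks, normalized by the maximum possible area,
#' giving a value in `[0, 1]`.  Because only ranks matter, the activity is
#' invariant to any monotone per-cell transformation of expression.
#'
#' @param expr a [lineage_expression()].
#' @param modules list of `regulon_module`s (see [extract_rgms()]).
#' @param top_frac fraction of top-ranked genes considered (default 0.05,
#'   the customary threshold for this style of scoring).
#' @param seed seed for tie-breaking jitter.
#' @return cells x modules numeric matrix in `[0, 1]`.
#' @export
aucell_activity <- function(expr, modules, top_frac = 0.05, seed = 1L) {
  stopifnot(top_frac > 0, top_frac < 1)
  x <- expr$values
  n <- ncol(x); m <- nrow(x)
  n_top <- ceiling(top_frac * n)
  member_idx <- lapply(modules, function(mod) {
    ix <- match(mod$members, expr$genes)
    ix[!is.na(ix)]
  })
  act <- matrix(0, m, length(modules),
                dimnames = list(expr$cells, names(modules)))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  jitter_mat <- matrix(stats::runif(m * n, 0, 1e-9), m, n)
  for (ci in seq_len(m)) {
    ranks <- rank(-(x[ci, ] + jitter_mat[ci, ]), ties.method = "first")
    for (k in seq_along(modules)) {
      ix <- member_idx[[k]]
      if (!length(ix)) next
      hit_ranks <- sort(ranks[ix])
      n_mem <- length(hit_ranks)
      # step AUC: cumulative hits summed over ranks 1..n_top
      hits_in <- hit_ranks[hit_ranks <= n_top]
      if (!length(hits_in)) next
      cum <- findInterval(seq_len(n_top), hits_in)
      max_area <- sum(pmin(seq_len(n_top), n_mem))
      act[ci, k] <- sum(cum) / max_area
    }
  }
  act
}

#' Write modules as GMT-style text
#'
#' One line per module: name, regulator description, then tab-separated
#' members (signed members suffixed with `-` when repressed).
#'
#' @param modules list of `regulon_module`s.
#' @param path output path.
#' @export
write_rgms <- function(modules, path) {
  lines <- vapply(names(modules), function(nm) {
    mod <- modules[[nm]]
    tagged <- ifelse(mod$signs == "repressed",
                     paste0(mod$members, "-"), mod$members)
    paste(c(nm, mod$kind, tagged), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
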