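# Self-contained synthetic fixtures: a planted lineage GRN with driver hubs
# wired into feedback loops, a prior network that buries it among decoy
# edges, and pseudotime-structured expression in which driver "programs"
# switch on or off along the trajectory.  Every pipeline stage can be
# exercised against the planted truth without external downloads.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic lineage scenario
#'
#' The planted regulatory network is grown with preferential attachment so
#' its out-degree distribution is heavy-tailed: each of `n_drivers` driver
#' genes regulates 10-30 targets, every other gene receives 1-2 regulators
#' chosen proportionally to current out-degree, the drivers are wired into
#' a directed cycle (plus a few target-to-driver feedback edges) so each
#' driver sits on a feedback loop.  The prior network adds
#' `decoy_ratio` times as many uniformly random decoy edges.  Expression is
#' simulated in linear space and `log1p`-transformed: each driver follows a
#' logistic activation or decay curve in pseudotime with amplitude
#' `effect_size`, targets respond linearly to their driver regulators with
#' random sign, and all genes carry Gaussian noise.  With
#' `preset = "null"` the prior is a degree-homogeneous random digraph of
#' matched density, the "truth" genes are a random draw and effect sizes
#' are zero, so no signal links labels to data.
#'
#' @param n_genes number of genes (>= 50).
#' @param m_cells number of cells (>= 100).
#' @param k_states number of pseudotime states the lineage is later binned
#'   into.
#' @param n_drivers number of planted driver genes.
#' @param decoy_ratio decoy:planted edge ratio in the prior (default 4).
#' @param effect_size amplitude of driver programs in linear expression
#'   units (default 3).
#' @param noise_sd Gaussian noise s.d. in linear space (default 0.5).
#' @param seed RNG seed; identical seeds give byte-identical scenarios.
#' @param preset `"default"` or `"null"` (see above).
#' @return object of class `synthetic_scenario`: `prior` and `planted_grn`
#'   ([gene_graph()]s), `drivers_truth`, `expression`
#'   (a [lineage_expression()] with pseudotime), and the generating
#'   parameters.
#' @export
make_scenario <- function(n_genes = 200L, m_cells = 500L, k_states = 4L,
                          n_drivers = 5L, decoy_ratio = 4,
                          effect_size = 3, noise_sd = 0.5, seed = 1L,
                          preset = c("default", "null")) {
  preset <- match.arg(preset)
  n_genes <- as.integer(n_genes); m_cells <- as.integer(m_cells)
  if (n_genes < 50L) stop("need at least 50 genes")
  if (m_cells < 100L) stop("need at least 100 cells")
  if (n_drivers * 10L > n_genes)
    stop("infeasible: n_drivers * 10 exceeds n_genes")
  if (preset == "null") effect_size <- 0
  with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    drivers <- sort(sample.int(n_genes, n_drivers))
    pl <- planted_edges(n_genes, drivers)
    if (preset == "null") {
      # matched density, homogeneous degrees, labels carry no information
      n_pl <- nrow(pl)
      prior_e <- random_edges(n_genes, round((1 + decoy_ratio) * n_pl),
                              avoid = NULL)
      planted <- gene_graph(genes)       # nothing planted
      prior <- gene_graph(genes, prior_e$from, prior_e$to)
    } else {
      planted <- gene_graph(genes, pl$from, pl$to)
      dec <- random_edges(n_genes, round(decoy_ratio * nrow(pl)), avoid = pl)
      prior <- gene_graph(genes,
                          c(pl$from, dec$from), c(pl$to, dec$to))
    }
    pt <- stats::runif(m_cells)
    expr_lin <- simulate_expression(n_genes, m_cells, pt, drivers,
                                    if (preset == "null")
                                      gene_graph(genes) else planted,
                                    effect_size, noise_sd)
    expr <- lineage_expression(log1p(expr_lin),
                               cells = sprintf("C%04d", seq_len(m_cells)),
                               genes = genes, pseudotime = pt)
    structure(list(seed = seed, n_genes = n_genes, m_cells = m_cells,
                   k_states = as.integer(k_states),
                   n_drivers = as.integer(n_drivers),
                   preset = preset, effect_size = effect_size,
                   noise_sd = noise_sd,
                   planted_grn = planted, prior = prior,
                   drivers_truth = genes[drivers], expression = expr),
              class = "synthetic_scenario")
  })
}

# planted edge table: driver hubs, preferential attachment, feedback loops
planted_edges <- function(n_genes, drivers) {
  from <- integer(); to <- integer()
  outdeg <- integer(n_genes)
  add <- function(f, t) {
    keep <- f != t
    from <<- c(from, f[keep]); to <<- c(to, t[keep])
    for (x in f[keep]) outdeg[x] <<- outdeg[x] + 1L
  }
  others <- setdiff(seq_len(n_genes), drivers)
  for (d in drivers) {
    k <- sample(10:30, 1L)
    add(rep.int(d, k), sample(others, k))
  }
  # non-driver genes acquire 1-2 regulators, rich-get-richer
  for (g in others) {
    k <- sample(1:2, 1L)
    w <- outdeg + 1L; w[g] <- 0
    regs <- sample.int(n_genes, k, prob = w)
    add(regs, rep.int(g, k))
  }
  # feedback: driver cycle plus a few target-to-driver back edges
  nd <- length(drivers)
  add(drivers, drivers[c(2:nd, 1L)])
  for (d in drivers[seq_len(min(3L, nd))]) {
    tg <- to[from == d]
    if (length(tg)) add(sample(tg, 1L), d)
  }
  key <- !duplicated(paste(from, to))
  data.frame(from = from[key], to = to[key])
}

random_edges <- function(n_genes, n_edges, avoid = NULL) {
  avoid_key <- if (is.null(avoid)) character() else paste(avoid$from, avoid$to)
  from <- integer(); to <- integer()
  seen <- character()
  while (length(from) < n_edges) {
    need <- n_edges - length(from)
    f <- sample.int(n_genes, 2L * need, replace = TRUE)
    t <- sample.int(n_genes, 2L * need, replace = TRUE)
    key <- paste(f, t)
    ok <- f != t & !(key %in% avoid_key) & !(key %in% seen) & !duplicated(key)
    f <- f[ok][seq_len(min(need, sum(ok)))]
    t <- t[ok][seq_len(min(need, sum(ok)))]
    from <- c(from, f); to <- c(to, t)
    seen <- c(seen, paste(f, t))
  }
  data.frame(from = from, to = to)
}

# linear-space expression; cells x genes
simulate_expression <- function(n_genes, m_cells, pt, drivers, planted,
                                effect_size, noise_sd) {
  x <- matrix(stats::rnorm(m_cells * n_genes, 0, noise_sd), m_cells, n_genes)
  base <- stats::runif(n_genes, 0.5, 1.5)
  x <- sweep(x, 2L, base, "+")
  if (effect_size > 0 && length(drivers)) {
    t0 <- stats::runif(length(drivers), 0.2, 0.8)
    up <- sample(c(TRUE, FALSE), length(drivers), replace = TRUE)
    curves <- sapply(seq_along(drivers), function(i) {
      a <- 1 / (1 + exp(-10 * (pt - t0[i])))
      if (up[i]) a else 1 - a
    })                                   # cells x drivers
    x[, drivers] <- x[, drivers] + effect_size * curves
    # targets respond linearly to their driver regulators, signed
    for (i in seq_along(drivers)) {
      d <- drivers[i]
      tg <- planted$edges$to[planted$edges$from == d]
      tg <- setdiff(tg, drivers)
      if (!length(tg)) next
      sgn <- sample(c(1, -1), length(tg), replace = TRUE, prob = c(0.6, 0.4))
      x[, tg] <- x[, tg] +
        outer(curves[, i], 0.8 * effect_size * sgn)
    }
  }
  pmax(x, 0)
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(paste0("synthetic_scenario (%s): %d genes x %d cells, ",
                     "%d planted drivers, prior %d edges (%d planted)\n"),
              x$preset, x$n_genes, x$m_cells, x$n_drivers,
              nrow(x$prior$edges), nrow(x$planted_grn$edges)))
  invisible(x)
}

#' A deterministic 12-gene worked example
#'
#' A hand-checkable instance: two 2-gene feedback loops driven by `T01` and
#' `T06`, a source hub `T10`, and simple pseudotime-structured expression
#' over 40 cells.  By exhaustive search the minimum feedback vertex set has
#' size 2 (one gene per loop) and the minimum dominating set size 3
#' (`T01`/`T02`-loop hub, `T06`, `T10`); with the single source `T10` the
#' feedback-vertex-set driver set has size 3.
#'
#' @return a `synthetic_scenario` (preset `"tiny"`).
#' @export
tiny_worked_example <- function() {
  genes <- sprintf("T%02d", 1:12)
  ed <- rbind(
    c(1, 2), c(2, 1), c(1, 3), c(1, 4), c(1, 5),
    c(6, 7), c(7, 6), c(6, 8), c(6, 9),
    c(10, 11), c(10, 12))
  prior <- gene_graph(genes, ed[, 1L], ed[, 2L])
  m <- 40L
  with_seed(42L, {
    pt <- seq(0, 1, length.out = m)
    x <- matrix(stats::rnorm(m * 12L, 1, 0.2), m, 12L)
    early <- 1 - 1 / (1 + exp(-10 * (pt - 0.4)))
    late <- 1 / (1 + exp(-10 * (pt - 0.6)))
    x[, c(1:5)] <- x[, c(1:5)] + 3 * early      # early program (T01 hub)
    x[, c(6:9)] <- x[, c(6:9)] + 3 * late       # late program (T06 hub)
    x[, 10:12] <- x[, 10:12] + 1.5 * late
    expr <- lineage_expression(log1p(pmax(x, 0)),
                               cells = sprintf("c%02d", seq_len(m)),
                               genes = genes, pseudotime = pt)
    structure(list(seed = 42L, n_genes = 12L, m_cells = m, k_states = 2L,
                   n_drivers = 2L, preset = "tiny", effect_size = 3,
                   noise_sd = 0.2,
                   planted_grn = prior, prior = prior,
                   drivers_truth = c("T01", "T06"), expression = expr),
              class = "synthetic_scenario")
  })
}

#' Write a scenario's inputs in the standard on-disk formats
#'
#' @param scenario a `synthetic_scenario`.
#' @param dir output directory (created if needed): `prior_edges.tsv`,
#'   `expression.tsv`, `pseudotime.tsv`, `drivers_truth.txt`,
#'   `planted_edges.tsv`.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pe <- scenario$prior$edges
  utils::write.table(
    data.frame(source = scenario$prior$nodes[pe$from],
               target = scenario$prior$nodes[pe$to], directed = 1L),
    file.path(dir, "prior_edges.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression(scenario$expression, file.path(dir, "expression.tsv"))
  utils::write.table(
    data.frame(cell_id = scenario$expression$cells,
               pseudotime = scenario$expression$pseudotime),
    file.path(dir, "pseudotime.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(scenario$drivers_truth, file.path(dir, "drivers_truth.txt"))
  ple <- scenario$planted_grn$edges
  utils::write.table(
    data.frame(source = scenario$planted_grn$nodes[ple$from],
               target = scenario$planted_grn$nodes[ple$to]),
    file.path(dir, "planted_edges.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
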