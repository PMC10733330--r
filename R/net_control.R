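# Driver-gene candidates by network control: minimum feedback vertex set
# (controlling the FVS plus all source nodes steers a nonlinear system with
# decaying dynamics among its attractors) and minimum dominating set (every
# gene is a driver or directly regulated by one).  Both problems are NP-hard
# 0-1 programs; they are reduced with safe graph rules to a small core and
# the core is solved exactly by branch-and-bound, with a time-limit fallback
# to the best incumbent.

## ---- internal mutable digraph --------------------------------------------

# adjacency-list digraph over original node ids; alive nodes only
ctrl_graph <- function(n, from, to) {
  g <- new.env(parent = emptyenv())
  g$n <- n
  g$succ <- vector("list", n)
  g$pred <- vector("list", n)
  for (i in seq_len(n)) { g$succ[[i]] <- integer(); g$pred[[i]] <- integer() }
  if (length(from)) {
    key <- !duplicated(paste(from, to))
    from <- from[key]; to <- to[key]
    for (k in seq_along(from)) {
      g$succ[[from[k]]] <- c(g$succ[[from[k]]], to[k])
      g$pred[[to[k]]] <- c(g$pred[[to[k]]], from[k])
    }
  }
  g$alive <- rep(TRUE, n)
  g
}

ctrl_copy <- function(g) {
  h <- new.env(parent = emptyenv())
  h$n <- g$n; h$succ <- g$succ; h$pred <- g$pred; h$alive <- g$alive
  h
}

ctrl_delete <- function(g, v) {
  for (w in g$succ[[v]]) g$pred[[w]] <- setdiff(g$pred[[w]], v)
  for (u in g$pred[[v]]) g$succ[[u]] <- setdiff(g$succ[[u]], v)
  g$succ[[v]] <- integer(); g$pred[[v]] <- integer()
  g$alive[v] <- FALSE
}

ctrl_add_edge <- function(g, u, v) {
  if (!(v %in% g$succ[[u]])) {
    g$succ[[u]] <- c(g$succ[[u]], v)
    g$pred[[v]] <- c(g$pred[[v]], u)
  }
}

ctrl_edges <- function(g) {
  from <- integer(); to <- integer()
  for (v in which(g$alive)) {
    if (length(g$succ[[v]])) {
      from <- c(from, rep.int(v, length(g$succ[[v]])))
      to <- c(to, g$succ[[v]])
    }
  }
  list(from = from, to = to)
}

# Kahn topological check, self-loops count as cycles
ctrl_is_acyclic <- function(g, exclude = integer()) {
  alive <- g$alive
  alive[exclude] <- FALSE
  indeg <- integer(g$n)
  for (v in which(alive)) {
    for (w in g$succ[[v]]) if (alive[w]) indeg[w] <- indeg[w] + 1L
    if (v %in% g$succ[[v]]) return(FALSE)
  }
  queue <- which(alive & indeg == 0L)
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (w in g$succ[[v]]) {
      if (!alive[w] || w == v) next
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  seen == sum(alive)
}

# Node set of a shortest directed cycle (BFS from each node back to
# itself); NULL if acyclic.  Self-loops return a single node.
ctrl_find_cycle <- function(g) {
  nodes <- which(g$alive)
  for (v in nodes) if (v %in% g$succ[[v]]) return(v)
  best <- NULL
  for (v in nodes) {
    par <- integer(g$n); dist <- rep(NA_integer_, g$n)
    queue <- v; dist[v] <- 0L
    done <- FALSE
    while (length(queue) && !done) {
      u <- queue[[1L]]; queue <- queue[-1L]
      if (!is.null(best) && dist[u] + 1L >= length(best)) break
      for (w in g$succ[[u]]) {
        if (w == v) {                     # edge u -> v closes the cycle
          path <- u
          while (path[[1L]] != v) path <- c(par[path[[1L]]], path)
          if (is.null(best) || length(path) < length(best)) best <- path
          done <- TRUE
          break
        }
        if (is.na(dist[w])) {
          dist[w] <- dist[u] + 1L; par[w] <- u
          queue <- c(queue, w)
        }
      }
    }
    if (!is.null(best) && length(best) == 2L) break
  }
  best
}

as_ctrl_graph <- function(grn) {
  if (inherits(grn, "lineage_grn")) {
    from <- grn$edges$from; to <- grn$edges$to
    if (is.null(from)) {
      from <- match(grn$edges$source, grn$nodes)
      to <- match(grn$edges$target, grn$nodes)
    }
    list(g = ctrl_graph(length(grn$nodes), from, to), nodes = grn$nodes)
  } else if (inherits(grn, "gene_graph")) {
    list(g = ctrl_graph(length(grn$nodes), grn$edges$from, grn$edges$to),
         nodes = grn$nodes)
  } else stop("expected a lineage_grn or gene_graph")
}

## ---- MFVS -----------------------------------------------------------------

# Safe contraction rules applied to fixpoint:
#   LOOP: a self-loop node must be in every FVS (forced in);
#   IN0/OUT0: a node in no cycle is removed (excluded);
#   IN1: a node with a single predecessor is merged into it;
#   OUT1: a node with a single successor is merged into it.
contract_steps <- function(g) {
  forced <- integer(); excluded <- integer()
  repeat {
    changed <- FALSE
    for (v in which(g$alive)) {
      if (v %in% g$succ[[v]]) {
        forced <- c(forced, v); ctrl_delete(g, v); changed <- TRUE
      } else if (length(g$pred[[v]]) == 0L || length(g$succ[[v]]) == 0L) {
        excluded <- c(excluded, v); ctrl_delete(g, v); changed <- TRUE
      } else if (length(g$pred[[v]]) == 1L) {
        u <- g$pred[[v]][[1L]]
        for (w in g$succ[[v]]) ctrl_add_edge(g, u, w)
        excluded <- c(excluded, v); ctrl_delete(g, v); changed <- TRUE
      } else if (length(g$succ[[v]]) == 1L) {
        w <- g$succ[[v]][[1L]]
        for (u in g$pred[[v]]) ctrl_add_edge(g, u, w)
        excluded <- c(excluded, v); ctrl_delete(g, v); changed <- TRUE
      }
      if (changed) break
    }
    if (!changed) break
  }
  list(forced = forced, excluded = excluded)
}

#' Contract a GRN for feedback-vertex-set solving
#'
#' Applies safe reductions to fixpoint: nodes with in- or out-degree zero
#' cannot sit on a cycle and are removed; nodes with a unique predecessor or
#' successor are merged into that neighbor; a self-loop (possibly created by
#' merging) forces its node into the feedback vertex set.  The reductions
#' preserve the optimum, so solving the reduced core and adding the forced
#' nodes solves the original instance.
#'
#' @param grn a `lineage_grn` or [gene_graph()].
#' @return list with `reduced` (data frame `from`, `to` in original node
#'   indices), `forced_in` and `excluded` (gene symbols), and `nodes`.
#' @export
contract_for_mfvs <- function(grn) {
  cg <- as_ctrl_graph(grn)
  res <- contract_steps(cg$g)
  ed <- ctrl_edges(cg$g)
  list(reduced = data.frame(from = ed$from, to = ed$to),
       forced_in = cg$nodes[res$forced],
       excluded = cg$nodes[res$excluded],
       nodes = cg$nodes)
}

# exact FVS on a contracted core by branching over a shortest cycle
fvs_branch <- function(g, best_size, deadline, state) {
  red <- contract_steps(g)
  forced <- red$forced
  if (length(forced) >= best_size) return(NULL)
  if (!any(g$alive)) return(forced)
  if (Sys.time() > deadline) { state$timed_out <- TRUE; return(NULL) }
  cyc <- ctrl_find_cycle(g)
  if (is.null(cyc)) return(forced)        # acyclic remainder
  best <- NULL
  for (v in cyc) {
    h <- ctrl_copy(g)
    ctrl_delete(h, v)
    sub <- fvs_branch(h, best_size - length(forced) - 1L, deadline, state)
    if (!is.null(sub)) {
      cand <- c(forced, v, sub)
      if (length(cand) < best_size) { best <- cand; best_size <- length(cand) }
    }
    if (state$timed_out) break
  }
  best
}

# greedy incumbent: repeatedly remove the node with max in*out degree
fvs_greedy <- function(g) {
  g <- ctrl_copy(g)
  sol <- integer()
  repeat {
    contract <- contract_steps(g)
    sol <- c(sol, contract$forced)
    if (!any(g$alive) || ctrl_is_acyclic(g)) break
    deg <- vapply(seq_len(g$n), function(v)
      if (g$alive[v]) length(g$pred[[v]]) * length(g$succ[[v]]) else -1L,
      numeric(1))
    v <- which.max(deg)
    sol <- c(sol, v)
    ctrl_delete(g, v)
  }
  sol
}

#' Solve the minimum feedback vertex set on a GRN
#'
#' Finds a minimum set of genes whose removal leaves the network without
#' feedback loops, then adds all source genes (in-degree zero), following
#' the extended feedback-vertex-set control scheme.  The instance is first
#' contracted ([contract_for_mfvs()]) and the core solved exactly by
#' branch-and-bound; if the time limit is hit the best incumbent is
#' returned with `optimal = FALSE`.  The acyclicity post-condition is
#' asserted on every solve.
#'
#' @param grn a `lineage_grn` or [gene_graph()].
#' @param time_limit wall-clock budget in seconds (default 600).
#' @return object of class `control_solution`: `method`, `driver_set`
#'   (gene symbols: FVS plus sources), `fvs_part`, `sources`, `objective`
#'   (`|driver_set|`), `optimal`, `solver_status`.
#' @export
solve_mfvs <- function(grn, time_limit = 600) {
  cg <- as_ctrl_graph(grn)
  g0 <- ctrl_copy(cg$g)
  sources <- which(vapply(seq_len(cg$g$n),
                          function(v) length(cg$g$pred[[v]]) == 0L,
                          logical(1)))
  deadline <- Sys.time() + time_limit
  state <- new.env(parent = emptyenv()); state$timed_out <- FALSE
  work <- ctrl_copy(cg$g)
  red <- contract_steps(work)
  forced <- red$forced
  if (any(work$alive)) {
    incumbent <- c(forced, fvs_greedy(work))
    exact <- fvs_branch(ctrl_copy(work), length(incumbent) - length(forced) + 1L,
                        deadline, state)
    fvs <- if (!is.null(exact)) c(forced, exact) else incumbent
  } else {
    fvs <- forced
  }
  optimal <- !state$timed_out
  if (!ctrl_is_acyclic(g0, exclude = fvs))
    stop("internal error: FVS removal leaves a cycle")
  drivers <- sort(unique(cg$nodes[c(fvs, sources)]))
  structure(list(method = "MFVS", driver_set = drivers,
                 fvs_part = sort(cg$nodes[fvs]),
                 sources = sort(cg$nodes[sources]),
                 objective = length(drivers), optimal = optimal,
                 solver_status = if (optimal) "optimal" else "time_limit"),
            class = "control_solution")
}

## ---- MDS ------------------------------------------------------------------

#' Reduce a GRN for minimum-dominating-set solving
#'
#' Safe rules to fixpoint: a gene with no predecessors can only dominate
#' itself, so it is forced into the set; genes dominated by a forced gene
#' are covered; covered genes with no uncovered successors impose no
#' constraint and offer no coverage, so they are dropped from the instance.
#'
#' @param grn a `lineage_grn` or [gene_graph()].
#' @return list with `forced_in` (gene symbols), `uncovered` (symbols still
#'   needing domination) and `candidates` (a named list: for each usable
#'   gene, the uncovered genes it would dominate).
#' @export
reduce_for_mds <- function(grn) {
  cg <- as_ctrl_graph(grn)
  g <- cg$g
  n <- g$n
  forced <- which(vapply(seq_len(n), function(v)
    g$alive[v] && length(g$pred[[v]]) == 0L, logical(1)))
  covered <- rep(FALSE, n)
  covered[forced] <- TRUE
  for (v in forced) covered[g$succ[[v]]] <- TRUE
  uncovered <- which(!covered)
  cands <- list()
  for (v in seq_len(n)) {
    if (v %in% forced) next
    cov <- intersect(c(v, g$succ[[v]]), uncovered)
    if (length(cov)) cands[[as.character(v)]] <- cov
  }
  list(forced_in = cg$nodes[forced],
       uncovered = cg$nodes[uncovered],
       candidates = stats::setNames(
         lapply(cands, function(ix) cg$nodes[ix]), names(cands)),
       nodes = cg$nodes,
       .idx = list(forced = forced, uncovered = uncovered, cands = cands))
}

# exact set cover by branch-and-bound; elements and sets are integer ids
cover_branch <- function(uncovered, cands, chosen, best, deadline, state) {
  if (!length(uncovered)) {
    if (is.null(best$sol) || length(chosen) < length(best$sol))
      best$sol <- chosen
    return(invisible(NULL))
  }
  if (Sys.time() > deadline) { state$timed_out <- TRUE; return(invisible(NULL)) }
  sizes <- vapply(cands, function(s) length(intersect(s, uncovered)),
                  integer(1))
  live <- sizes > 0L
  if (!any(live)) return(invisible(NULL)) # infeasible branch
  lb <- length(chosen) + ceiling(length(uncovered) / max(sizes[live]))
  if (!is.null(best$sol) && lb >= length(best$sol)) return(invisible(NULL))
  # branch on the element with fewest covering sets
  ncov <- vapply(uncovered, function(e)
    sum(vapply(cands[live], function(s) e %in% s, logical(1))), integer(1))
  e <- uncovered[which.min(ncov)]
  covering <- names(cands)[live][vapply(cands[live], function(s) e %in% s,
                                        logical(1))]
  covering <- covering[order(-sizes[covering])]
  for (cn in covering) {
    cover_branch(setdiff(uncovered, cands[[cn]]), cands,
                 c(chosen, as.integer(cn)), best, deadline, state)
    if (state$timed_out) break
  }
  invisible(NULL)
}

mds_greedy <- function(uncovered, cands) {
  chosen <- integer()
  while (length(uncovered)) {
    sizes <- vapply(cands, function(s) length(intersect(s, uncovered)),
                    integer(1))
    if (max(sizes) == 0L) break
    cn <- names(cands)[which.max(sizes)]
    chosen <- c(chosen, as.integer(cn))
    uncovered <- setdiff(uncovered, cands[[cn]])
  }
  chosen
}

#' Solve the minimum dominating set on a GRN
#'
#' Finds a minimum set of genes such that every gene either belongs to the
#' set or has a predecessor (a direct regulator) in it.  The instance is
#' reduced ([reduce_for_mds()]) and the remaining covering problem solved
#' exactly by branch-and-bound; on time-out the greedy incumbent is
#' returned with `optimal = FALSE`.  The domination post-condition is
#' asserted on every solve.
#'
#' @param grn a `lineage_grn` or [gene_graph()].
#' @param time_limit wall-clock budget in seconds (default 600).
#' @return a `control_solution` with `method = "MDS"`.
#' @export
solve_mds <- function(grn, time_limit = 600) {
  red <- reduce_for_mds(grn)
  idx <- red$.idx
  deadline <- Sys.time() + time_limit
  state <- new.env(parent = emptyenv()); state$timed_out <- FALSE
  chosen <- integer()
  if (length(idx$uncovered)) {
    cands <- lapply(idx$cands, identity)
    greedy <- mds_greedy(idx$uncovered, cands)
    best <- new.env(parent = emptyenv()); best$sol <- greedy
    cover_branch(idx$uncovered, cands, integer(), best, deadline, state)
    chosen <- best$sol
  }
  optimal <- !state$timed_out
  cg <- as_ctrl_graph(grn)
  dom <- sort(unique(c(idx$forced, chosen)))
  covered <- rep(FALSE, cg$g$n)
  covered[dom] <- TRUE
  for (v in dom) covered[cg$g$succ[[v]]] <- TRUE
  if (!all(covered))
    stop("internal error: dominating set misses ", sum(!covered), " node(s)")
  drivers <- sort(cg$nodes[dom])
  structure(list(method = "MDS", driver_set = drivers,
                 objective = length(drivers), optimal = optimal,
                 solver_status = if (optimal) "optimal" else "time_limit"),
            class = "control_solution")
}

#' @export
print.control_solution <- function(x, ...) {
  cat(sprintf("%s control solution: %d driver gene(s) [%s]\n",
              x$method, x$objective, x$solver_status))
  invisible(x)
}

#' Union of the two control-based candidate sets
#'
#' @param mfvs,mds `control_solution` objects.
#' @return sorted character vector of candidate driver genes.
#' @export
candidate_union <- function(mfvs, mds) {
  sort(unique(c(mfvs$driver_set, mds$driver_set)))
}
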