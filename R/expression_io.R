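#' Lineage expression container
#'
#' Holds a cells x genes log-normalized expression matrix together with a
#' per-cell pseudotime for one developmental lineage, and (after
#' [bin_pseudotime()]) an integer state label per cell.
#'
#' @param values numeric cells x genes matrix, finite and non-negative.
#' @param cells character cell ids (unique).
#' @param genes character gene symbols (unique).
#' @param pseudotime numeric per-cell pseudotime, or `NULL`.
#' @param state_labels optional integer per-cell state in `1..K`.
#' @return an object of class `lineage_expression`.
#' @export
lineage_expression <- function(values, cells = rownames(values),
                               genes = colnames(values),
                               pseudotime = NULL, state_labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cells) || is.null(genes))
    stop("cell ids and gene symbols are required")
  cells <- trimws(as.character(cells)); genes <- trimws(as.character(genes))
  if (anyDuplicated(cells)) stop("cell ids must be unique")
  if (anyDuplicated(genes)) stop("gene symbols must be unique")
  stopifnot(nrow(values) == length(cells), ncol(values) == length(genes))
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and non-negative")
  if (!is.null(pseudotime)) {
    pseudotime <- as.numeric(pseudotime)
    stopifnot(length(pseudotime) == length(cells))
    if (any(!is.finite(pseudotime))) stop("pseudotime must be finite")
  }
  dimnames(values) <- list(cells, genes)
  structure(list(values = values, cells = cells, genes = genes,
                 pseudotime = pseudotime, state_labels = state_labels),
            class = "lineage_expression")
}

#' @export
print.lineage_expression <- function(x, ...) {
  cat(sprintf("lineage_expression: %d cells x %d genes%s%s\n",
              length(x$cells), length(x$genes),
              if (!is.null(x$pseudotime)) ", with pseudotime" else "",
              if (!is.null(x$state_labels))
                sprintf(", %d states", max(x$state_labels)) else ""))
  invisible(x)
}

#' Read an expression matrix
#'
#' Accepts either delimited text (cells in rows, header row of gene symbols,
#' first column of cell ids) or MatrixMarket triplet format with sidecar
#' `genes.txt` / `cells.txt` name files in the same directory.
#'
#' @param path path to a `.csv`/`.tsv`/`.txt` table or a `.mtx` file.
#' @param pseudotime_path optional TSV `cell_id<TAB>pseudotime`; joined by
#'   cell id.
#' @param sep separator for delimited text (guessed from the extension when
#'   `NULL`).
#' @return a [lineage_expression()].
#' @export
read_expression <- function(path, pseudotime_path = NULL, sep = NULL) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    gf <- file.path(dir, "genes.txt"); cf <- file.path(dir, "cells.txt")
    if (!file.exists(gf) || !file.exists(cf))
      stop("MTX input requires sidecar genes.txt and cells.txt next to ", path)
    genes <- readLines(gf); cells <- readLines(cf)
    if (nrow(m) != length(cells) || ncol(m) != length(genes))
      stop(sprintf("MTX shape %dx%d does not match %d cells x %d genes",
                   nrow(m), ncol(m), length(cells), length(genes)))
    expr <- lineage_expression(m, cells = cells, genes = genes)
  } else {
    if (is.null(sep))
      sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                             check.names = FALSE, stringsAsFactors = FALSE)
    expr <- lineage_expression(as.matrix(tab))
  }
  if (!is.null(pseudotime_path))
    expr <- attach_pseudotime(expr, read_pseudotime(pseudotime_path))
  expr
}

#' Read a per-cell pseudotime table
#'
#' @param path TSV with columns `cell_id` and `pseudotime` (header optional
#'   but recommended).
#' @return data.frame with columns `cell_id`, `pseudotime`.
#' @export
read_pseudotime <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("pseudotime table needs cell_id and pseudotime")
  data.frame(cell_id = trimws(as.character(tab[[1L]])),
             pseudotime = as.numeric(tab[[2L]]),
             stringsAsFactors = FALSE)
}

attach_pseudotime <- function(expr, pt) {
  idx <- match(expr$cells, pt$cell_id)
  if (anyNA(idx))
    stop("pseudotime missing for ", sum(is.na(idx)), " cell(s), e.g. ",
         expr$cells[which(is.na(idx))[1L]])
  expr$pseudotime <- pt$pseudotime[idx]
  expr
}

#' Write an expression matrix as delimited text
#'
#' @param expr a [lineage_expression()].
#' @param path output path (TSV; cells in rows).
#' @export
write_expression <- function(expr, path) {
  tab <- data.frame(cell_id = expr$cells, expr$values, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a lineage GRN as TSV
#'
#' The GRN table has columns `source`, `target`, `weight`, `origin`.
#'
#' @param grn a `lineage_grn` (see [select_edges()]).
#' @param path output path.
#' @export
write_grn <- function(grn, path) {
  utils::write.table(grn$edges[, c("source", "target", "weight", "origin")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grn
#' @export
read_grn <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  nodes <- sort(unique(c(tab$source, tab$target)))
  structure(list(nodes = nodes,
                 edges = data.frame(source = tab$source, target = tab$target,
                                    weight = tab$weight,
                                    origin = if ("origin" %in% names(tab))
                                      tab$origin else "prior",
                                    stringsAsFactors = FALSE),
                 k_d = NA_integer_),
            class = "lineage_grn")
}

#' Write a driver report as JSON (plus a TSV score table)
#'
#' @param report a `driver_report` (see [identify_drivers()]).
#' @param path output JSON path; a sibling `<path>.scores.tsv` is written
#'   with per-gene influence scores.
#' @export
write_report <- function(report, path) {
  out <- list(
    candidates_mfvs = report$candidates_mfvs,
    candidates_mds = report$candidates_mds,
    drivers = report$drivers,
    metrics = report$metrics,
    mfvs_optimal = report$mfvs$optimal,
    mds_optimal = report$mds$optimal
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(report$scores, paste0(path, ".scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
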