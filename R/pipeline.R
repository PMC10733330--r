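#' Pipeline configuration
#'
#' Every tunable of the pipeline with its default.  Unknown keys are
#' rejected so config files cannot silently misspell an option.
#'
#' @param ... named overrides of the defaults listed below.
#' @return a named list of class `run_config`.
#' @details Keys and defaults: `k_states` (4), `fdr_cutoff` (0.01),
#'   `augment_coexpression` (TRUE), `coexpr_top_frac` (0.01),
#'   `coexpr_rho_min` (0.6), `hidden_dim` (128), `out_dim` (64), `heads`
#'   (4), `tau` (0.25), `epochs` (350), `learning_rate` (1e-4),
#'   `weight_decay` (5e-4), `use_de_encoding` (TRUE), `corrupt_each_epoch`
#'   (TRUE), `k_d` (8), `mu` (0.5), `lambda` (0.8), `top_n` (100),
#'   `min_rgm_size` (10), `aucell_top_frac` (0.05), `time_limit` (60),
#'   `repeats` (20), `aggregate` ("weights" or "none"), `seed` (1).
#' @export
run_config <- function(...) {
  defaults <- list(
    k_states = 4L, fdr_cutoff = 0.01,
    augment_coexpression = TRUE, coexpr_top_frac = 0.01,
    coexpr_rho_min = 0.6,
    hidden_dim = 128L, out_dim = 64L, heads = 4L, tau = 0.25,
    epochs = 350L, learning_rate = 1e-4, weight_decay = 5e-4,
    use_de_encoding = TRUE, corrupt_each_epoch = TRUE,
    k_d = 8L, mu = 0.5, lambda = 0.8, top_n = 100L,
    min_rgm_size = 10L, aucell_top_frac = 0.05,
    time_limit = 60, repeats = 20L, aggregate = "weights", seed = 1L)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over)[1L]))
    over <- over[[1L]]
  if (length(over) && (is.null(names(over)) || any(!nzchar(names(over)))))
    stop("all config overrides must be named")
  # when a key is given twice, the later (caller-side) value wins
  over <- over[!duplicated(names(over), fromLast = TRUE)]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  if (!cfg$aggregate %in% c("weights", "none"))
    stop("aggregate must be 'weights' or 'none'")
  structure(cfg, class = "run_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path config file path (`.yaml`/`.yml` or `.json`).
#' @return a [run_config()].
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  run_config(vals)
}

#' Run the full driver-regulator pipeline
#'
#' Executes preparation (pseudotime binning, differential-expression
#' magnitudes), encoder training (`repeats` times with consecutive seeds,
#' degree-scaled attention weights averaged across repeats when
#' `aggregate = "weights"`; with `aggregate = "none"` only the first repeat
#' is used), GRN selection, network-control driver identification,
#' influence ranking, regulon-like module extraction and per-cell module
#' activities.  Fully deterministic given `seed` and `repeats`.
#'
#' @param prior a [gene_graph()] prior network.
#' @param expr a [lineage_expression()] with pseudotime.
#' @param config a [run_config()].
#' @param out_dir if non-`NULL`, artifacts are written there: `grn.tsv`,
#'   `report.json` (+ score TSV), `rgms.gmt`, `activity.tsv`,
#'   `manifest.json`.
#' @return list of class `pipeline_result`: `grn`, `report`, `rgms`,
#'   `activity`, `de`, `weights` (aggregated per-layer tables), `losses`
#'   (per repeat), `graph` (analysis graph), `config`, `manifest`.
#' @export
run_pipeline <- function(prior, expr, config = run_config(),
                         out_dir = NULL) {
  if (is.null(expr$pseudotime)) stop("expression lacks pseudotime")
  graph <- restrict_to_expressed(prior, expr)
  if (config$augment_coexpression)
    graph <- augment_with_coexpression(graph, expr,
                                       top_frac = config$coexpr_top_frac,
                                       rho_min = config$coexpr_rho_min)
  expr <- bin_pseudotime(expr, config$k_states)
  de <- compute_logfc(expr, fdr_cutoff = config$fdr_cutoff)
  n_rep <- if (config$aggregate == "none") 1L else as.integer(config$repeats)
  losses <- vector("list", n_rep)
  layer_sum <- NULL
  wt <- NULL
  for (r in seq_len(n_rep)) {
    ecfg <- encoder_config(hidden_dim = config$hidden_dim,
                           out_dim = config$out_dim, heads = config$heads,
                           tau = config$tau, epochs = config$epochs,
                           learning_rate = config$learning_rate,
                           weight_decay = config$weight_decay,
                           seed = config$seed + r - 1L,
                           use_de_encoding = config$use_de_encoding,
                           corrupt_each_epoch = config$corrupt_each_epoch)
    enc <- train_encoder(graph, expr, de, ecfg)
    losses[[r]] <- enc$losses
    wt <- scale_attention(enc$attention, graph)
    if (is.null(layer_sum)) {
      layer_sum <- wt$layers
    } else {
      for (l in 1:2) layer_sum[[l]] <- layer_sum[[l]] + wt$layers[[l]]
    }
  }
  wt$layers <- lapply(layer_sum, function(x) x / n_rep)
  combined <- combine_layers(wt$layers[[1L]], wt$layers[[2L]],
                             mu = config$mu)
  grn <- select_edges(wt, graph, k_d = config$k_d, combined = combined)
  report <- identify_drivers(grn, lam = config$lambda,
                             top_n = config$top_n,
                             time_limit = config$time_limit)
  rgms <- extract_rgms(grn, report$drivers, de, expr,
                       min_size = config$min_rgm_size)
  activity <- aucell_activity(expr, rgms,
                              top_frac = config$aucell_top_frac,
                              seed = config$seed)
  manifest <- list(
    package_version = as.character(utils::packageVersion("fatedrivers")),
    r_version = R.version.string,
    seed = config$seed, repeats = n_rep, aggregate = config$aggregate,
    n_genes = length(graph$nodes), n_cells = length(expr$cells),
    n_prior_edges = nrow(graph$edges), n_grn_edges = nrow(grn$edges),
    config = unclass(config))
  res <- structure(list(grn = grn, report = report, rgms = rgms,
                        activity = activity, de = de, weights = wt,
                        losses = losses, graph = graph, config = config,
                        manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_grn(grn, file.path(out_dir, "grn.tsv"))
    write_report(report, file.path(out_dir, "report.json"))
    write_rgms(rgms, file.path(out_dir, "rgms.gmt"))
    utils::write.table(
      data.frame(cell_id = rownames(activity), activity,
                 check.names = FALSE),
      file.path(out_dir, "activity.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  print(x$grn)
  print(x$report)
  cat(sprintf("  %d regulon-like module(s); activity matrix %d x %d\n",
              length(x$rgms), nrow(x$activity), ncol(x$activity)))
  invisible(x)
}
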