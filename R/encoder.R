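#' Encoder configuration
#'
#' Hyperparameters of the directional graph-attention encoder.  Defaults
#' follow the published setting for this architecture family: two layers,
#' four heads, hidden size 128, output embedding size 64, softmax
#' temperature 0.25, Adam with learning rate 1e-4 and weight decay 5e-4,
#' 350 training epochs.
#'
#' @param hidden_dim width of the first-layer output per direction.
#' @param out_dim width of the final gene embedding (both directions
#'   concatenated).
#' @param heads number of attention heads per direction.
#' @param tau softmax temperature (< 1 sharpens attention).
#' @param epochs training epochs.
#' @param learning_rate,weight_decay Adam settings.
#' @param seed RNG seed controlling initialization and corruption.
#' @param use_de_encoding if `FALSE` the differential-expression scaling is
#'   frozen at a constant, reducing the score to pure absolute-cosine
#'   attention (ablation switch).
#' @param corrupt_each_epoch draw a fresh feature shuffle every epoch
#'   (standard for contrastive graph training) or reuse one shuffle.
#' @return a list of class `encoder_config`.
#' @export
encoder_config <- function(hidden_dim = 128L, out_dim = 64L, heads = 4L,
                           tau = 0.25, epochs = 350L, learning_rate = 1e-4,
                           weight_decay = 5e-4, seed = 1L,
                           use_de_encoding = TRUE,
                           corrupt_each_epoch = TRUE) {
  stopifnot(tau > 0, heads >= 1L, hidden_dim >= 1L, out_dim >= 1L,
            epochs >= 1L)
  if (hidden_dim %% heads != 0L)
    stop("hidden_dim must be divisible by heads")
  if (out_dim %% (2L * heads) != 0L)
    stop("out_dim must be divisible by 2*heads")
  structure(list(hidden_dim = as.integer(hidden_dim),
                 out_dim = as.integer(out_dim), heads = as.integer(heads),
                 tau = tau, epochs = as.integer(epochs),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 seed = as.integer(seed),
                 use_de_encoding = isTRUE(use_de_encoding),
                 corrupt_each_epoch = isTRUE(corrupt_each_epoch)),
            class = "encoder_config")
}

#' Differential-expression attention scaling
#'
#' `D_j = sigmoid(c * l_j + d)`: a learnable monotone mapping from a gene's
#' differential-expression magnitude to a multiplicative attention factor in
#' (0, 1), letting strongly perturbed genes amplify their influence on
#' neighbors.
#'
#' @param l per-gene non-negative magnitudes.
#' @param c,d scalars (learned during training).
#' @return numeric vector in (0, 1).
#' @export
de_scalar <- function(l, c, d) {
  stopifnot(all(is.finite(l)))
  1 / (1 + exp(-(c * l + d)))
}

#' Cosine attention score between two projected genes
#'
#' The unnormalized attention of center gene i toward neighbor gene j is the
#' absolute cosine between their projections, scaled by the neighbor's
#' differential-expression factor: only the intensity of the relationship
#' matters, not its sign.  Zero-norm projections score 0.
#'
#' @param hi,hj projected feature vectors (`Wa hi`, `Wb hj`).
#' @param dj scaling factor for the neighbor gene in (0, 1].
#' @return a scalar in `[0, dj]`.
#' @export
attention_score <- function(hi, hj, dj = 1) {
  ni <- sqrt(sum(hi^2)); nj <- sqrt(sum(hj^2))
  if (ni == 0 || nj == 0) return(0)
  dj * abs(sum(hi * hj) / (ni * nj))
}

#' Temperature-softmax normalization of neighborhood scores
#'
#' @param scores unnormalized scores over a neighborhood (self included).
#' @param tau temperature.
#' @return coefficients summing to 1.
#' @export
normalize_attention <- function(scores, tau = 0.25) {
  z <- scores / tau
  e <- exp(z - max(z))
  e / sum(e)
}

#' Shuffle node features for contrastive negatives
#'
#' Randomly reassigns the expression profile of each gene to a different
#' position (a plain uniform shuffle) while the graph topology stays fixed.
#'
#' @param h node-feature matrix (genes in rows).
#' @param seed optional seed for the permutation.
#' @return the row-permuted matrix.
#' @export
corrupt_features <- function(h, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h[sample.int(nrow(h)), , drop = FALSE]
}

#' Contrastive mutual-information loss (reference implementation)
#'
#' Binary cross-entropy of a bilinear discriminator between real embeddings
#' and a global summary versus shuffled-feature embeddings; the quantity the
#' encoder minimizes.  A discriminator stuck at probability 0.5 gives
#' `log(2)`.
#'
#' @param h_real,h_corrupt embedding matrices (genes x dim).
#' @param summary global summary vector (sigmoid of the mean real
#'   embedding).
#' @param m bilinear discriminator matrix.
#' @return non-negative scalar.
#' @export
dgi_loss <- function(h_real, h_corrupt, summary, m) {
  lp <- as.vector(h_real %*% m %*% summary)
  ln_ <- as.vector(h_corrupt %*% m %*% summary)
  softplus <- function(z) ifelse(z > 30, z, log1p(exp(z)))
  (sum(softplus(-lp)) + sum(softplus(ln_))) / (length(lp) + length(ln_))
}

## ---- internal: architecture ----------------------------------------------

# pair lists (center, neighbor) per direction, self pairs appended last so
# pair k of the first |E| rows maps to prior edge k
encoder_pairs <- function(graph) {
  n <- n_genes(graph)
  e <- graph$edges
  list(
    "in"  = list(ci = c(e$to, seq_len(n)),   ni = c(e$from, seq_len(n))),
    "out" = list(ci = c(e$from, seq_len(n)), ni = c(e$to, seq_len(n)))
  )
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

encoder_dims <- function(cfg, f_in) {
  fh1 <- cfg$hidden_dim %/% cfg$heads
  fh2 <- cfg$out_dim %/% (2L * cfg$heads)
  d1 <- 2L * cfg$heads * fh1             # layer-1 concat width
  d2 <- 2L * cfg$heads * fh2             # final embedding width (= out_dim)
  list(f_in = f_in, fh = c(fh1, fh2), dcat = c(d1, d2),
       lin = c(f_in, d1))                # per-layer input widths
}

encoder_init_params <- function(cfg, f_in) {
  dims <- encoder_dims(cfg, f_in)
  params <- list(c = matrix(1), d = matrix(0))
  for (l in 1:2) {
    fi <- dims$lin[l]; fh <- dims$fh[l]; dc <- dims$dcat[l]
    params[[paste0("bn_gamma", l)]] <- matrix(1, 1L, fi)
    params[[paste0("bn_beta", l)]] <- matrix(0, 1L, fi)
    for (dir in c("in", "out")) {
      # per-head projections kept as contiguous column blocks; each block
      # initialized with its own Glorot fan so heads stay exchangeable
      params[[sprintf("Wa_%d_%s", l, dir)]] <-
        do.call(cbind, replicate(cfg$heads, glorot(fi, fh), simplify = FALSE))
      params[[sprintf("Wb_%d_%s", l, dir)]] <-
        do.call(cbind, replicate(cfg$heads, glorot(fi, fh), simplify = FALSE))
    }
    params[[paste0("ffn_W", l)]] <- glorot(dc, dc)
    params[[paste0("ffn_b", l)]] <- matrix(0, 1L, dc)
  }
  params[["M"]] <- glorot(dims$dcat[2L], dims$dcat[2L])
  params
}

# One full forward pass; returns the embedding node plus attention values.
encoder_forward <- function(tape, pnodes, x_node, pairs, cfg, l_vec) {
  n <- nrow(x_node$value)
  if (cfg$use_de_encoding) {
    de <- ad_de_scalar(tape, l_vec, pnodes$c, pnodes$d)
  } else {
    de <- ad_const(tape, rep(0.5, n))
  }
  h <- x_node
  att <- list()
  for (l in 1:2) {
    hn <- ad_batchnorm(tape, h,
                       pnodes[[paste0("bn_gamma", l)]],
                       pnodes[[paste0("bn_beta", l)]])
    dir_outs <- list()
    att[[l]] <- list()
    for (dir in c("in", "out")) {
      pr <- pairs[[dir]]
      pa <- ad_matmul(tape, hn, pnodes[[sprintf("Wa_%d_%s", l, dir)]])
      pb <- ad_matmul(tape, hn, pnodes[[sprintf("Wb_%d_%s", l, dir)]])
      raw <- ad_edge_abs_cos_mh(tape, pa, pb, pr$ci, pr$ni, cfg$heads)
      sc <- ad_scale_by_de_mh(tape, raw, de, pr$ni)
      alpha <- ad_group_softmax_mh(tape, sc, pr$ci, cfg$tau)
      agg <- ad_gat_aggregate_mh(tape, alpha, pa, pr$ci, pr$ni, cfg$heads)
      dir_outs[[dir]] <- ad_gelu(tape, agg)
      att[[l]][[dir]] <- alpha$value
    }
    hcat <- ad_cbind(tape, dir_outs)
    ff <- ad_matmul(tape, hcat, pnodes[[paste0("ffn_W", l)]])
    ff <- ad_add_bias(tape, ff, pnodes[[paste0("ffn_b", l)]])
    h <- ad_gelu(tape, ff)
  }
  list(h = h, att = att, de = de$value)
}

## ---- training -------------------------------------------------------------

#' Train the directional graph-attention encoder
#'
#' Two-layer, two-channel (in-coming / out-going) multi-head graph-attention
#' network with absolute-cosine attention, temperature softmax over each
#' neighborhood (self included), batch normalization before and a
#' feedforward block after each layer, GELU activations, and a learnable
#' sigmoid scaling of each neighbor's differential-expression magnitude.
#' Trained unsupervised by maximizing the mutual information between gene
#' embeddings and a global summary against feature-shuffled negatives, with
#' Adam.  Node features are the per-gene standardized log-normalized
#' expression profiles across cells.
#'
#' @param graph a [gene_graph()] restricted to expressed genes (node order
#'   defines the feature rows).
#' @param expr a [lineage_expression()] covering the graph's genes.
#' @param de a `diffexp_profile` from [compute_logfc()], or `NULL` for
#'   uniform scaling.
#' @param cfg an [encoder_config()].
#' @return list of class `trained_encoder`: `embeddings` (genes x out_dim),
#'   `attention` (an `attention_record`), `de_encoding` (list with `c`, `d`,
#'   per-gene `D`), `losses` (per-epoch), `config`.
#' @export
train_encoder <- function(graph, expr, de = NULL, cfg = encoder_config()) {
  cols <- match(graph$nodes, expr$genes)
  if (anyNA(cols)) stop("graph contains genes absent from expression")
  x <- t(expr$values[, cols, drop = FALSE])       # genes x cells
  mu <- rowMeans(x); sdv <- apply(x, 1L, stats::sd)
  sdv[sdv == 0] <- 1
  x <- (x - mu) / sdv
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 genes")
  l_vec <- if (is.null(de)) rep(0, n) else {
    li <- match(graph$nodes, de$genes)
    if (anyNA(li)) stop("diffexp profile misses graph genes")
    de$l[li]
  }
  pairs <- encoder_pairs(graph)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)
  params <- encoder_init_params(cfg, ncol(x))
  mstate <- lapply(params, function(p) p * 0)
  vstate <- lapply(params, function(p) p * 0)
  losses <- numeric(cfg$epochs)
  perm <- sample.int(n)                  # used when corruption is frozen
  for (epoch in seq_len(cfg$epochs)) {
    if (cfg$corrupt_each_epoch) perm <- sample.int(n)
    tape <- ad_tape()
    pnodes <- lapply(params, function(p) ad_param(tape, p))
    x_real <- ad_const(tape, x)
    x_corr <- ad_const(tape, x[perm, , drop = FALSE])
    fw_r <- encoder_forward(tape, pnodes, x_real, pairs, cfg, l_vec)
    fw_c <- encoder_forward(tape, pnodes, x_corr, pairs, cfg, l_vec)
    s <- ad_sigmoid(tape, ad_colmeans(tape, fw_r$h))
    lp <- ad_bilinear_logits(tape, fw_r$h, pnodes$M, s)
    ln_ <- ad_bilinear_logits(tape, fw_c$h, pnodes$M, s)
    loss <- ad_dgi_loss(tape, lp, ln_)
    losses[epoch] <- loss$value
    if (!is.finite(loss$value))
      stop("non-finite training loss at epoch ", epoch)
    ad_backward(tape, loss)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    for (nm in names(params)) {
      g <- pnodes[[nm]]$grad
      if (is.null(g)) next
      g <- g + cfg$weight_decay * params[[nm]]
      mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g
      vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g^2
      mhat <- mstate[[nm]] / (1 - b1^epoch)
      vhat <- vstate[[nm]] / (1 - b2^epoch)
      params[[nm]] <- params[[nm]] -
        cfg$learning_rate * mhat / (sqrt(vhat) + eps)
    }
  }
  # final deterministic forward on real features for export
  tape <- ad_tape()
  pnodes <- lapply(params, function(p) ad_param(tape, p))
  fw <- encoder_forward(tape, pnodes, ad_const(tape, x), pairs, cfg, l_vec)
  emb <- fw$h$value
  rownames(emb) <- graph$nodes
  att <- attention_record(graph, pairs, fw$att, cfg$heads)
  structure(list(embeddings = emb, attention = att,
                 de_encoding = list(c = params$c[1L], d = params$d[1L],
                                    D = fw$de),
                 losses = losses, config = cfg),
            class = "trained_encoder")
}

#' Attention record
#'
#' Normalized attention coefficients per layer (1, 2), direction
#' (`in` = aggregation from regulators, `out` = from targets) and head, over
#' (center, neighbor) pairs: the prior edges first (in edge order), then the
#' self pairs.
#'
#' @param graph the [gene_graph()] the encoder ran on.
#' @param pairs internal pair lists.
#' @param att nested list of per-layer/direction alpha matrices
#'   (pairs x heads).
#' @param heads number of heads.
#' @return object of class `attention_record`.
#' @keywords internal
attention_record <- function(graph, pairs, att, heads) {
  structure(list(nodes = graph$nodes, n_edges = nrow(graph$edges),
                 pairs = pairs, alpha = att, heads = heads),
            class = "attention_record")
}

#' Check the softmax normalization invariant of an attention record
#'
#' For every layer, direction and head, the coefficients over each center's
#' neighborhood (self included) must sum to 1.
#'
#' @param record an `attention_record`.
#' @param tol tolerance on the per-center sums.
#' @return the maximum absolute deviation from 1 (invisibly); errors if it
#'   exceeds `tol`.
#' @export
check_attention_sums <- function(record, tol = 1e-6) {
  worst <- 0
  for (l in 1:2) for (dir in c("in", "out")) {
    a <- record$alpha[[l]][[dir]]
    ci <- record$pairs[[dir]]$ci
    for (k in seq_len(ncol(a))) {
      sums <- rowsum(a[, k], ci)
      worst <- max(worst, max(abs(sums - 1)))
    }
  }
  if (worst > tol) stop("attention rows deviate from 1 by ", worst)
  invisible(worst)
}
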