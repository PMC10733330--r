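# Minimal reverse-mode automatic differentiation on dense matrices.
#
# The attention encoder needs gradients through matrix products, group-wise
# softmax over graph neighborhoods, cosine similarities gathered along edge
# lists, batch normalization and a bilinear discriminator.  Rather than
# hand-chaining those derivatives through a deep architecture, each forward
# op records a closure on a tape; ad_backward() replays the tape in reverse.
# Gradient correctness is established against central finite differences in
# the test suite.

ad_tape <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$n <- 0L
  env
}

# value: numeric matrix/vector; parents: list of nodes; backward: function(g)
# returning a list of parent gradients (same order as parents).
ad_node <- function(tape, value, parents = list(), backward = NULL,
                    param = FALSE) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  node$param <- param
  tape$n <- tape$n + 1L
  node$id <- tape$n
  tape$nodes[[tape$n]] <- node
  node
}

ad_param <- function(tape, value) ad_node(tape, value, param = TRUE)
ad_const <- function(tape, value) ad_node(tape, value)

ad_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

# Backpropagate from scalar node `loss` (seed gradient 1).
ad_backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in seq(tape$n, 1L)) {
    node <- tape$nodes[[i]]
    if (is.null(node$backward) || is.null(node$grad)) next
    gs <- node$backward(node$grad)
    for (k in seq_along(node$parents)) {
      if (!is.null(gs[[k]])) ad_accum(node$parents[[k]], gs[[k]])
    }
  }
  invisible(NULL)
}

ad_zero_grads <- function(tape) {
  for (node in tape$nodes) node$grad <- NULL
  invisible(NULL)
}

## ---- elementary ops -------------------------------------------------------

ad_matmul <- function(tape, x, w) {
  xv <- x$value; wv <- w$value
  ad_node(tape, xv %*% wv, list(x, w), function(g) {
    list(tcrossprod(g, wv), crossprod(xv, g))
  })
}

ad_add <- function(tape, x, y) {
  ad_node(tape, x$value + y$value, list(x, y), function(g) list(g, g))
}

# add a length-ncol bias row-vector to every row
ad_add_bias <- function(tape, x, b) {
  ad_node(tape, sweep(x$value, 2L, as.vector(b$value), "+"), list(x, b),
          function(g) list(g, colSums(g)))
}

ad_gelu <- function(tape, x) {
  xv <- x$value
  phi <- stats::pnorm(xv)
  ad_node(tape, xv * phi, list(x), function(g) {
    list(g * (phi + xv * stats::dnorm(xv)))
  })
}

ad_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  ad_node(tape, s, list(x), function(g) list(g * s * (1 - s)))
}

# Batch normalization over rows (per-column standardization), with learnable
# per-column scale gamma and shift beta; always in "training" statistics
# mode since the whole graph is one batch.
ad_batchnorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  n <- nrow(xv)
  mu <- colMeans(xv)
  xc <- sweep(xv, 2L, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, istd, "*")
  gv <- as.vector(gamma$value); bv <- as.vector(beta$value)
  out <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  ad_node(tape, out, list(x, gamma, beta), function(g) {
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    gxhat <- sweep(g, 2L, gv, "*")
    # standard batch-norm backward
    t1 <- colSums(gxhat)
    t2 <- colSums(gxhat * xhat)
    dx <- sweep(gxhat, 2L, t1 / n) - sweep(xhat, 2L, t2 / n, "*")
    dx <- sweep(dx, 2L, istd, "*")
    list(dx, dgamma, dbeta)
  })
}

ad_cbind <- function(tape, nodes) {
  widths <- vapply(nodes, function(n) ncol(n$value), integer(1))
  ad_node(tape, do.call(cbind, lapply(nodes, function(n) n$value)), nodes,
          function(g) {
            off <- 0L
            lapply(widths, function(w) {
              out <- g[, off + seq_len(w), drop = FALSE]
              off <<- off + w
              out
            })
          })
}

## ---- encoder-specific ops -------------------------------------------------

# Differential-expression scaling D = sigmoid(c * l + d), l fixed, c and d
# learnable scalars (1x1 matrices).
ad_de_scalar <- function(tape, l, c_par, d_par) {
  cv <- c_par$value[1L]; dv <- d_par$value[1L]
  s <- 1 / (1 + exp(-(cv * l + dv)))
  ad_node(tape, s, list(c_par, d_par), function(g) {
    w <- g * s * (1 - s)
    list(matrix(sum(w * l)), matrix(sum(w)))
  })
}

# Absolute cosine similarity between rows Pa[ci, ] and Pb[ni, ] for a fixed
# pair list (ci = center row indices, ni = neighbor row indices).  Zero-norm
# projections give score 0 (flat gradient).
# NOTE: the edge/group ops below assume `ci` and `ni` are integer indices
# that each cover 1..nrow (guaranteed in the encoder by the appended self
# pairs), so rowsum(x, idx, reorder = TRUE) returns one row per node in
# node order.
ad_edge_abs_cos <- function(tape, pa, pb, ci, ni) {
  A <- pa$value[ci, , drop = FALSE]
  B <- pb$value[ni, , drop = FALSE]
  ne <- length(ci); fd <- ncol(A)
  dot <- .rowSums(A * B, ne, fd)
  na2 <- .rowSums(A * A, ne, fd); nb2 <- .rowSums(B * B, ne, fd)
  denom <- sqrt(na2 * nb2)
  bad <- denom <= 0
  denom[bad] <- 1
  cosv <- dot / denom
  cosv[bad] <- 0
  sgn <- sign(cosv)
  val <- abs(cosv)
  n_pa <- nrow(pa$value); n_pb <- nrow(pb$value)
  ad_node(tape, val, list(pa, pb), function(g) {
    gc <- g * sgn                        # through the absolute value
    gc[bad] <- 0
    inv <- gc / denom
    na2s <- na2; na2s[bad] <- 1; nb2s <- nb2; nb2s[bad] <- 1
    dA <- inv * B - (gc * cosv / na2s) * A
    dB <- inv * A - (gc * cosv / nb2s) * B
    list(rowsum(dA, ci, reorder = TRUE), rowsum(dB, ni, reorder = TRUE))
  })
}

# Multiply per-pair scores by the neighbor's DE scaling D[ni].
ad_scale_by_de <- function(tape, scores, de, ni) {
  dv <- de$value
  sv <- scores$value
  ad_node(tape, sv * dv[ni], list(scores, de), function(g) {
    list(g * dv[ni], as.vector(rowsum(g * sv, ni, reorder = TRUE)))
  })
}

# Temperature softmax within groups (one group per center node).  Scores
# are stabilized by subtracting the global maximum before exponentiation
# (equivalent to any per-group shift).
ad_group_softmax <- function(tape, scores, group, tau) {
  sv <- scores$value / tau
  e <- exp(sv - max(sv))
  gsum <- rowsum(e, group, reorder = TRUE)
  alpha <- e / gsum[group]
  ad_node(tape, alpha, list(scores), function(g) {
    dotg <- rowsum(alpha * g, group, reorder = TRUE)
    list((alpha * (g - dotg[group])) / tau)
  })
}

# out[i, ] = sum over pairs with center i of alpha_e * P[ni_e, ].
# Every center in 1..n appears at least once (self pair).
ad_gat_aggregate <- function(tape, alpha, p, ci, ni, n) {
  pv <- p$value
  pn <- pv[ni, , drop = FALSE]
  msg <- alpha$value * pn
  out <- rowsum(msg, ci, reorder = TRUE)
  ad_node(tape, out, list(alpha, p), function(g) {
    dmsg <- g[ci, , drop = FALSE]
    dalpha <- .rowSums(dmsg * pn, length(ci), ncol(pv))
    dp <- rowsum(dmsg * alpha$value, ni, reorder = TRUE)
    list(dalpha, dp)
  })
}

ad_colmeans <- function(tape, x) {
  n <- nrow(x$value)
  ad_node(tape, matrix(colMeans(x$value), 1L), list(x), function(g) {
    list(matrix(rep(as.vector(g) / n, each = n), nrow = n))
  })
}

# logits_i = h_i' M s'  (s a 1 x F node)
ad_bilinear_logits <- function(tape, h, m, s) {
  hv <- h$value; mv <- m$value; sv <- matrix(as.vector(s$value), ncol = 1L)
  ms <- mv %*% sv
  ad_node(tape, as.vector(hv %*% ms), list(h, m, s), function(g) {
    gv <- matrix(g, ncol = 1L)
    dh <- gv %*% t(ms)
    dm <- crossprod(hv, gv) %*% t(sv)
    ds <- t(mv) %*% crossprod(hv, gv)
    list(dh, dm, matrix(as.vector(ds), 1L))
  })
}

# Contrastive (DGI) binary cross-entropy: minimize
#   mean over 2N terms of softplus(-pos) and softplus(neg), with the 1/(2N)
#   averaging of the underlying mutual-information bound.
ad_dgi_loss <- function(tape, logits_pos, logits_neg) {
  lp <- logits_pos$value; ln_ <- logits_neg$value
  n <- length(lp)
  softplus <- function(z) ifelse(z > 30, z, log1p(exp(z)))
  val <- (sum(softplus(-lp)) + sum(softplus(ln_))) / (2 * n)
  ad_node(tape, val, list(logits_pos, logits_neg), function(g) {
    list(g * (-1 / (1 + exp(lp))) / (2 * n),
         g * (1 / (1 + exp(-ln_))) / (2 * n))
  })
}

## ---- multi-head batched variants ------------------------------------------
# Heads are stored as contiguous column blocks of width fh; these variants
# process all K heads of one direction in a single op, which is
# mathematically identical to the per-head ops but far cheaper in R.

# per-head absolute cosine: pa, pb are n x (K*fh); returns ne x K
ad_edge_abs_cos_mh <- function(tape, pa, pb, ci, ni, heads) {
  A <- pa$value[ci, , drop = FALSE]
  B <- pb$value[ni, , drop = FALSE]
  kf <- ncol(A); fh <- kf %/% heads
  mask <- matrix(0, kf, heads)
  mask[cbind(seq_len(kf), rep(seq_len(heads), each = fh))] <- 1
  expand <- rep(seq_len(heads), each = fh)
  dot <- (A * B) %*% mask
  na2 <- (A * A) %*% mask
  nb2 <- (B * B) %*% mask
  denom <- sqrt(na2 * nb2)
  bad <- denom <= 0
  denom[bad] <- 1
  cosv <- dot / denom
  cosv[bad] <- 0
  sgn <- sign(cosv)
  ad_node(tape, abs(cosv), list(pa, pb), function(g) {
    gc <- g * sgn
    gc[bad] <- 0
    inv <- gc / denom
    na2s <- na2; na2s[bad] <- 1
    nb2s <- nb2; nb2s[bad] <- 1
    ca <- gc * cosv / na2s
    cb <- gc * cosv / nb2s
    dA <- inv[, expand, drop = FALSE] * B - ca[, expand, drop = FALSE] * A
    dB <- inv[, expand, drop = FALSE] * A - cb[, expand, drop = FALSE] * B
    list(rowsum(dA, ci, reorder = TRUE), rowsum(dB, ni, reorder = TRUE))
  })
}

# scores ne x K, scaled by D[ni] (recycled down columns)
ad_scale_by_de_mh <- function(tape, scores, de, ni) {
  dv <- de$value
  sv <- scores$value
  ad_node(tape, sv * dv[ni], list(scores, de), function(g) {
    list(g * dv[ni], rowSums(rowsum(g * sv, ni, reorder = TRUE)))
  })
}

# column-wise group softmax (ne x K scores)
ad_group_softmax_mh <- function(tape, scores, group, tau) {
  sv <- scores$value / tau
  e <- exp(sv - max(sv))
  gsum <- rowsum(e, group, reorder = TRUE)
  alpha <- e / gsum[group, , drop = FALSE]
  dimnames(alpha) <- NULL
  ad_node(tape, alpha, list(scores), function(g) {
    dotg <- rowsum(alpha * g, group, reorder = TRUE)
    list((alpha * (g - dotg[group, , drop = FALSE])) / tau)
  })
}

# aggregate all heads at once: alpha ne x K, p n x (K*fh); the output is the
# head-concatenated n x (K*fh) feature block
ad_gat_aggregate_mh <- function(tape, alpha, p, ci, ni, heads) {
  pv <- p$value
  kf <- ncol(pv); fh <- kf %/% heads
  expand <- rep(seq_len(heads), each = fh)
  mask <- matrix(0, kf, heads)
  mask[cbind(seq_len(kf), expand)] <- 1
  pn <- pv[ni, , drop = FALSE]
  av <- alpha$value
  msg <- pn * av[, expand, drop = FALSE]
  out <- rowsum(msg, ci, reorder = TRUE)
  dimnames(out) <- NULL
  ad_node(tape, out, list(alpha, p), function(g) {
    dmsg <- g[ci, , drop = FALSE]
    dalpha <- (dmsg * pn) %*% mask
    dp <- rowsum(dmsg * av[, expand, drop = FALSE], ni, reorder = TRUE)
    list(dalpha, dp)
  })
}
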