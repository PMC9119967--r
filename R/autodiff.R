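# Minimal tape-based reverse-mode automatic differentiation.
#
# Every op takes and returns "nodes" (list(id, v)); the tape records the
# value, parent ids and a backward closure returning gradients aligned with
# the parents. This is enough machinery for the message-passing network:
# dense affine maps, ReLU, batch normalization, segment softmax aggregation,
# segment pooling and a binary cross-entropy head, plus gather/scatter for
# per-edge work. Gradients are exact; correctness is pinned by finite
# difference checks in the test suite.

tape_new <- function() {
  t <- new.env(parent = emptyenv())
  t$n <- 0L
  t$vals <- vector("list", 256L)
  t$parents <- vector("list", 256L)
  t$bw <- vector("list", 256L)
  t
}

ad_node <- function(tape, value, parents = integer(0), backward = NULL) {
  # force arguments before taking an id: parents must precede children on the
  # tape (R's lazy evaluation would otherwise invert the order)
  force(value); force(parents); force(backward)
  id <- tape$n + 1L
  if (id > length(tape$vals)) {
    grow <- length(tape$vals) * 2L
    length(tape$vals) <- grow; length(tape$parents) <- grow; length(tape$bw) <- grow
  }
  tape$n <- id
  tape$vals[[id]] <- value
  tape$parents[[id]] <- parents
  if (!is.null(backward)) tape$bw[[id]] <- backward
  list(id = id, v = value)
}

ad_const <- function(tape, value) ad_node(tape, value)

# Backward pass from a scalar (or seeded) root; returns a list of gradients
# indexed by node id (NULL where the node does not influence the root).
tape_backward <- function(tape, root, seed = NULL) {
  grads <- vector("list", tape$n)
  grads[[root$id]] <- if (is.null(seed)) {
    if (length(root$v) != 1L) stop("backward root must be scalar unless seeded")
    matrix(1, 1, 1)
  } else seed
  for (id in tape$n:1) {
    g <- grads[[id]]
    if (is.null(g)) next
    bwf <- tape$bw[[id]]
    if (is.null(bwf)) next
    pg <- bwf(g)
    ps <- tape$parents[[id]]
    for (k in seq_along(ps)) {
      contrib <- pg[[k]]
      if (is.null(contrib)) next
      pid <- ps[k]
      grads[[pid]] <- if (is.null(grads[[pid]])) contrib else grads[[pid]] + contrib
    }
  }
  grads
}

## ---- primitive ops ---------------------------------------------------------

op_matmul <- function(tape, A, B) {
  ad_node(tape, A$v %*% B$v, c(A$id, B$id),
          local({ Av <- A$v; Bv <- B$v
            function(g) list(g %*% t(Bv), t(Av) %*% g) }))
}

op_add <- function(tape, A, B) {
  ad_node(tape, A$v + B$v, c(A$id, B$id), function(g) list(g, g))
}

# add a length-ncol vector to every row
op_add_vec <- function(tape, A, b) {
  ad_node(tape, sweep(A$v, 2, b$v, "+"), c(A$id, b$id),
          function(g) list(g, colSums(g)))
}

op_add_scalar_const <- function(tape, A, k) {
  ad_node(tape, A$v + k, A$id, function(g) list(g))
}

op_mul <- function(tape, A, B) {
  ad_node(tape, A$v * B$v, c(A$id, B$id),
          local({ Av <- A$v; Bv <- B$v
            function(g) list(g * Bv, g * Av) }))
}

# multiply matrix A by scalar node s
op_scale <- function(tape, A, s) {
  ad_node(tape, A$v * as.numeric(s$v), c(A$id, s$id),
          local({ Av <- A$v; sv <- as.numeric(s$v)
            function(g) list(g * sv, sum(g * Av)) }))
}

# scale each row of A by the matching entry of column vector c (length nrow)
op_rowscale <- function(tape, A, cvec) {
  cv <- as.numeric(cvec$v)
  ad_node(tape, A$v * cv, c(A$id, cvec$id),
          local({ Av <- A$v
            function(g) list(g * cv, rowSums(g * Av)) }))
}

op_relu <- function(tape, A) {
  mask <- A$v > 0
  ad_node(tape, A$v * mask, A$id, function(g) list(g * mask))
}

op_gather <- function(tape, A, idx) {
  nA <- nrow(A$v)
  ad_node(tape, A$v[idx, , drop = FALSE], A$id,
          function(g) {
            acc <- rowsum(g, group = idx)
            out <- matrix(0, nA, ncol(g))
            out[as.integer(rownames(acc)), ] <- acc
            list(out)
          })
}

op_concat_cols <- function(tape, A, B) {
  ka <- ncol(A$v)
  ad_node(tape, cbind(A$v, B$v), c(A$id, B$id),
          function(g) list(g[, seq_len(ka), drop = FALSE],
                           g[, -seq_len(ka), drop = FALSE]))
}

op_sum <- function(tape, A) {
  dims <- dim(A$v)
  ad_node(tape, matrix(sum(A$v), 1, 1), A$id,
          function(g) list(matrix(as.numeric(g), dims[1], dims[2])))
}

# Segment descriptor used by the segment ops: precomputed once per batch.
make_segments <- function(seg, n_out) {
  uniq <- sort(unique(seg))
  list(seg = seg, uniq = uniq, pos = match(seg, uniq), n_out = n_out)
}

place_segments <- function(acc, segs, ncol_) {
  out <- matrix(0, segs$n_out, ncol_)
  out[segs$uniq, ] <- acc
  out
}

# Feature-wise learnable softmax aggregation:
#   out[v, j] = sum_e softmax_e(beta * M[e, j]) * M[e, j]  over edges e -> v.
# Segments with no edges yield zero rows (isolated nodes).
op_seg_softmax_agg <- function(tape, M, segs, beta) {
  b <- as.numeric(beta$v)
  shift <- max(M$v, 0)      # constant shift cancels inside each segment
  EX <- exp(b * (M$v - shift))
  denom <- rowsum(EX, group = segs$pos)
  W <- EX / denom[segs$pos, , drop = FALSE]
  acc <- rowsum(W * M$v, group = segs$pos)
  outv <- place_segments(acc, segs, ncol(M$v))
  ad_node(tape, outv, c(M$id, beta$id),
          local({ Mv <- M$v
            function(g) {
              ge <- g[segs$seg, , drop = FALSE]
              oute <- outv[segs$seg, , drop = FALSE]
              gM <- ge * W * (1 + b * (Mv - oute))
              gb <- sum(ge * W * Mv * (Mv - oute))
              list(gM, gb)
            } }))
}

# Power-mean aggregation (reference implementation for the ablation axis):
#   out[v, j] = ( mean_e max(M,eps)^p )^(1/p), fixed exponent p.
op_seg_powermean_agg <- function(tape, M, segs, p = 1, eps = 1e-7) {
  Mc <- pmax(M$v, eps)
  cnt <- as.numeric(table(factor(segs$pos, levels = seq_along(segs$uniq))))
  mp <- rowsum(Mc^p, group = segs$pos) / cnt
  acc <- mp^(1 / p)
  outv <- place_segments(acc, segs, ncol(M$v))
  ad_node(tape, outv, M$id,
          function(g) {
            ge <- g[segs$seg, , drop = FALSE]
            oute <- outv[segs$seg, , drop = FALSE]
            mpe <- pmax(oute, eps)
            gM <- ge * (mpe^(1 - p)) * (Mc^(p - 1)) / cnt[segs$pos] * (M$v > eps)
            list(gM)
          })
}

op_seg_pool <- function(tape, A, segs, method = c("mean", "sum", "max")) {
  method <- match.arg(method)
  if (method == "max") {
    n <- segs$n_out; k <- ncol(A$v)
    outv <- matrix(-Inf, n, k); arg <- matrix(NA_integer_, n, k)
    for (e in seq_len(nrow(A$v))) {
      v <- segs$seg[e]
      better <- A$v[e, ] > outv[v, ]
      outv[v, better] <- A$v[e, better]; arg[v, better] <- e
    }
    outv[is.infinite(outv)] <- 0
    return(ad_node(tape, outv, A$id, function(g) {
      gA <- matrix(0, nrow(A$v), ncol(A$v))
      for (v in seq_len(n)) for (j in seq_len(k))
        if (!is.na(arg[v, j])) gA[arg[v, j], j] <- gA[arg[v, j], j] + g[v, j]
      list(gA)
    }))
  }
  acc <- rowsum(A$v, group = segs$pos)
  if (method == "mean") {
    cnt <- as.numeric(table(factor(segs$pos, levels = seq_along(segs$uniq))))
    acc <- acc / cnt
  }
  outv <- place_segments(acc, segs, ncol(A$v))
  ad_node(tape, outv, A$id,
          function(g) {
            ge <- g[segs$seg, , drop = FALSE]
            if (method == "mean") {
              cnt <- as.numeric(table(factor(segs$pos, levels = seq_along(segs$uniq))))
              ge <- ge / cnt[segs$pos]
            }
            list(ge)
          })
}

# Batch normalization over rows. `state` is a mutable environment holding the
# running first/second moments under `key`; training mode uses batch moments
# and updates the running ones, evaluation mode uses the stored moments.
op_batchnorm <- function(tape, A, gamma, beta, state, key, training,
                         momentum = 0.1, eps = 1e-5) {
  x <- A$v
  if (training) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    var <- colMeans(xc^2)
    st <- state[[key]]
    if (is.null(st)) st <- list(mean = mu * 0, var = mu * 0 + 1)
    state[[key]] <- list(mean = (1 - momentum) * st$mean + momentum * mu,
                         var  = (1 - momentum) * st$var + momentum * var)
  } else {
    st <- state[[key]]
    if (is.null(st)) st <- list(mean = numeric(ncol(x)), var = rep(1, ncol(x)))
    mu <- st$mean; var <- st$var
    xc <- sweep(x, 2, mu)
  }
  istd <- 1 / sqrt(var + eps)
  xhat <- sweep(xc, 2, istd, "*")
  y <- sweep(sweep(xhat, 2, gamma$v, "*"), 2, beta$v, "+")
  ad_node(tape, y, c(A$id, gamma$id, beta$id),
          function(g) {
            dgamma <- colSums(g * xhat)
            dbeta <- colSums(g)
            dxhat <- sweep(g, 2, gamma$v, "*")
            if (!training) {
              dx <- sweep(dxhat, 2, istd, "*")
            } else {
              N <- nrow(x)
              dvar <- colSums(dxhat * xc) * (-0.5) * istd^3
              dmu <- colSums(sweep(dxhat, 2, -istd, "*")) + dvar * colMeans(-2 * xc)
              dx <- sweep(dxhat, 2, istd, "*") +
                sweep(xc, 2, 2 * dvar / N, "*") +
                matrix(dmu / N, N, ncol(x), byrow = TRUE)
            }
            list(dx, dgamma, dbeta)
          })
}

# Mean binary cross-entropy over logits (numerically stable log1p form).
op_bce_logits <- function(tape, Z, y) {
  z <- as.numeric(Z$v)
  n <- length(z)
  sp <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
  loss <- mean(sp - y * z)
  ad_node(tape, matrix(loss, 1, 1), Z$id,
          function(g) {
            p <- 1 / (1 + exp(-z))
            list(matrix(as.numeric(g) * (p - y) / n, ncol = 1))
          })
}
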