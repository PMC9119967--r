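# Deep message-passing GCN module: input embedding, pre-activation residual
# blocks around the message-construct / softmax-aggregate / MLP-update
# convolution, optional dilated k-NN neighborhoods, and graph pooling.

MESSAGE_EPS <- 1e-7

#' GCN module configuration
#'
#' @param num_layers Number of message-passing residual blocks (default 20).
#' @param hidden_dim Embedding width (default 128).
#' @param aggregation `"softmax"` (learnable inverse temperature, default) or
#'   `"powermean"` (reference implementation, fixed exponent `powermean_p`).
#' @param pooling Graph readout: `"mean"` (default), `"max"` or `"sum"`.
#' @param dilation Optional `list(k =, d =)`; when set, each layer replaces
#'   the chemical-bond neighborhoods with dilated k-NN neighborhoods computed
#'   in the current embedding space (edge features are then absent and treated
#'   as zero).
#' @param mlp_hidden_multiplier Width multiplier of the update MLP's hidden
#'   layer (default 2).
#' @param dropout Dropout fraction in `[0, 1)` applied inside blocks during
#'   training (default 0).
#' @param powermean_p Exponent for power-mean aggregation (default 1).
#' @return A `gcn_config` list.
#' @export
gcn_config <- function(num_layers = 20L, hidden_dim = 128L,
                       aggregation = c("softmax", "powermean"),
                       pooling = c("mean", "max", "sum"),
                       dilation = NULL, mlp_hidden_multiplier = 2L,
                       dropout = 0, powermean_p = 1) {
  aggregation <- match.arg(aggregation)
  pooling <- match.arg(pooling)
  stopifnot(num_layers >= 0, hidden_dim >= 1,
            dropout >= 0, dropout < 1, mlp_hidden_multiplier >= 1)
  if (!is.null(dilation)) {
    stopifnot(is.list(dilation), dilation$k >= 1, dilation$d >= 1)
  }
  structure(list(num_layers = as.integer(num_layers),
                 hidden_dim = as.integer(hidden_dim),
                 aggregation = aggregation, pooling = pooling,
                 dilation = dilation,
                 mlp_hidden_multiplier = as.integer(mlp_hidden_multiplier),
                 dropout = dropout, powermean_p = powermean_p),
            class = "gcn_config")
}

# Desk-scale profile: small enough that full curricula run in seconds.
#' @rdname gcn_config
#' @export
desk_config <- function() gcn_config(num_layers = 4L, hidden_dim = 32L)

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize parameters of one GCN module
#'
#' Weights use Glorot-uniform initialization; batch-norm scale/shift start at
#' 1/0; each layer's aggregation inverse temperature `beta` starts at 1.
#' Running normalization statistics live in the mutable `bn_state`
#' environment so evaluation mode is deterministic.
#'
#' @param config A [gcn_config()].
#' @param atom_dim,bond_dim Input one-hot lengths (defaults from the schemas).
#' @return A `module_params` list.
#' @export
init_module_params <- function(config,
                               atom_dim = sum(atom_feature_schema()$sizes),
                               bond_dim = sum(bond_feature_schema()$sizes)) {
  h <- config$hidden_dim
  hm <- h * config$mlp_hidden_multiplier
  layers <- lapply(seq_len(config$num_layers), function(l) {
    list(bn_gamma = rep(1, h), bn_beta = rep(0, h),
         beta_agg = 1,
         w1 = glorot(h, hm), b1 = rep(0, hm),
         bn2_gamma = rep(1, hm), bn2_beta = rep(0, hm),
         w2 = glorot(hm, h), b2 = rep(0, h))
  })
  structure(list(w_node = glorot(atom_dim, h), b_node = rep(0, h),
                 w_edge = glorot(bond_dim, h), b_edge = rep(0, h),
                 layers = layers,
                 bn_state = new.env(parent = emptyenv())),
            class = "module_params")
}

## ---- batched graphs --------------------------------------------------------

# Stack graphs block-diagonally: node/edge features row-bound, edge indices
# offset, per-node graph ids for pooling. Works for a single graph too.
graph_batch <- function(graphs) {
  if (inherits(graphs, "mol_graph")) graphs <- list(graphs)
  n <- vapply(graphs, function(g) g$node_count, numeric(1))
  offs <- c(0, cumsum(n))[seq_along(graphs)]
  nfeat <- do.call(rbind, lapply(graphs, function(g) g$node_features))
  efeat <- do.call(rbind, lapply(graphs, function(g) g$edge_features))
  edges <- do.call(rbind, mapply(function(g, o) {
    if (nrow(g$edges) == 0) matrix(numeric(0), ncol = 2) else g$edges + o
  }, graphs, offs, SIMPLIFY = FALSE))
  bond_of_edge <- unlist(lapply(graphs, function(g) g$bond_id))  # graph-local ids
  graph_of_edge <- unlist(mapply(function(g, i) rep(i, nrow(g$edges)),
                                 graphs, seq_along(graphs), SIMPLIFY = FALSE))
  gid <- rep(seq_along(graphs), times = n)
  N <- sum(n)
  list(n_graphs = length(graphs), n_nodes = N,
       nfeat = nfeat, efeat = efeat,
       src = edges[, 1], dst = edges[, 2],
       bond_of_edge = as.integer(bond_of_edge),
       graph_of_edge = as.integer(graph_of_edge),
       node_offsets = offs,
       agg_segs = make_segments(if (nrow(edges)) edges[, 2] else integer(0), N),
       pool_segs = make_segments(gid, length(graphs)))
}

# Bind parameter leaves into tape nodes once per forward; records node ids by
# path so gradients can be collected back into the parameter structure.
param_binder <- function(tape, registry_prefix = "", registry = NULL) {
  cache <- new.env(parent = emptyenv())
  bind <- function(value, path) {
    if (is.null(cache[[path]])) {
      nd <- ad_node(tape, if (is.matrix(value)) value else matrix(value, nrow = 1))
      cache[[path]] <- nd
      if (!is.null(registry)) registry[[paste0(registry_prefix, path)]] <- nd$id
    }
    cache[[path]]
  }
  bind
}

## ---- spec operations (standalone numeric forms) ----------------------------

#' Project one-hot features to the hidden dimension
#'
#' @param graph A `mol_graph`.
#' @param params A `module_params`.
#' @return List with `node` (node_count x hidden) and `edge`
#'   (directed-edge x hidden) embedding matrices.
#' @export
embed_inputs <- function(graph, params) {
  node <- sweep(graph$node_features %*% params$w_node, 2, params$b_node, "+")
  edge <- if (nrow(graph$edge_features) > 0) {
    sweep(graph$edge_features %*% params$w_edge, 2, params$b_edge, "+")
  } else {
    matrix(0, 0, ncol(node))
  }
  list(node = node, edge = edge)
}

#' Message construction
#'
#' `ReLU(x_u + x_e) + eps`: the message from neighbour `u` to `v` along edge
#' features `x_e`, kept strictly positive by a small additive constant so the
#' softmax aggregation is well behaved.
#'
#' @param x_v,x_u,x_e Numeric vectors of equal length (receiver embedding,
#'   neighbour embedding, edge embedding). `x_v` is accepted for interface
#'   completeness; the chosen message form uses only `x_u` and `x_e`.
#' @return Numeric vector.
#' @export
message_construct <- function(x_v, x_u, x_e) {
  stopifnot(length(x_u) == length(x_e))
  pmax(x_u + x_e, 0) + MESSAGE_EPS
}

#' Learnable softmax aggregation
#'
#' Feature-wise softmax-weighted sum of the neighbour messages:
#' `M_v[j] = sum_u softmax_u(beta * M_vu[j]) * M_vu[j]`. `beta = 0` recovers
#' the arithmetic mean; large `beta` approaches the feature-wise maximum.
#'
#' @param messages Matrix with one row per neighbour message.
#' @param beta Scalar inverse temperature.
#' @return Aggregated message vector; the zero vector for an empty set.
#' @export
aggregate_softmax <- function(messages, beta = 1) {
  if (is.null(dim(messages))) messages <- matrix(messages, nrow = 1)
  if (nrow(messages) == 0) return(numeric(ncol(messages)))
  out <- numeric(ncol(messages))
  for (j in seq_len(ncol(messages))) {
    m <- messages[, j]
    w <- exp(beta * (m - max(m)))
    w <- w / sum(w)
    out[j] <- sum(w * m)
  }
  out
}

#' Node update MLP
#'
#' `MLP(x_v + M_v)` with one hidden layer: linear, normalization (identity
#' when `norm = NULL`), ReLU, linear.
#'
#' @param x_v Node embedding; `m_v` aggregated message.
#' @param w1,b1,w2,b2 MLP weights.
#' @param norm Optional function applied after the first linear layer.
#' @return Updated embedding vector.
#' @export
node_update <- function(x_v, m_v, w1, b1, w2, b2, norm = NULL) {
  z <- as.numeric((x_v + m_v) %*% w1 + b1)
  if (!is.null(norm)) z <- norm(z)
  as.numeric(pmax(z, 0) %*% w2 + b2)
}

#' Dilated k-NN neighborhoods
#'
#' For each node, ranks all other nodes by ascending Euclidean distance in
#' the embedding space (ties broken by node index) and keeps every `d`-th of
#' the first `k*d`, yielding `k` neighbours.
#'
#' @param emb Node-embedding matrix (one row per node).
#' @param k Number of neighbours; `d` dilation rate.
#' @return List of neighbour index vectors, one per node.
#' @export
dilated_knn <- function(emb, k, d = 1L) {
  n <- nrow(emb)
  if (k * d > n - 1) stop("k*d exceeds available nodes", call. = FALSE)
  lapply(seq_len(n), function(v) {
    dist2 <- rowSums(sweep(emb, 2, emb[v, ])^2)
    ord <- order(dist2[-v])               # among other nodes, ties by index
    others <- seq_len(n)[-v][ord]
    others[seq(d, k * d, by = d)]
  })
}

#' Graph pooling
#'
#' @param emb Node-embedding matrix (at least one row).
#' @param method `"mean"`, `"max"` or `"sum"`.
#' @return Pooled vector of length `ncol(emb)`.
#' @export
pool_nodes <- function(emb, method = c("mean", "max", "sum")) {
  method <- match.arg(method)
  if (nrow(emb) == 0) stop("cannot pool an empty graph", call. = FALSE)
  switch(method,
         mean = colMeans(emb),
         max = apply(emb, 2, max),
         sum = colSums(emb))
}

## ---- tape forward ----------------------------------------------------------

# Forward pass of one module over a batched graph, on a tape.
# Returns list(pooled, x0, edge_coeff) of tape nodes. `edge_coeff`, when
# requested, is a per-directed-edge multiplier (value 1) applied to the raw
# bond feature rows; its gradient drives the augmentation engine.
gcn_forward_tape <- function(tape, batch, params, config, training = FALSE,
                             bind = NULL, prefix = "", with_edge_coeff = FALSE,
                             registry = NULL) {
  if (is.null(bind)) bind <- param_binder(tape, prefix, registry)
  h <- config$hidden_dim
  nfeat <- ad_const(tape, batch$nfeat)
  X0 <- op_add_vec(tape, op_matmul(tape, nfeat, bind(params$w_node, "w_node")),
                   bind(params$b_node, "b_node"))
  n_edges <- length(batch$src)
  edge_coeff <- NULL
  if (n_edges > 0) {
    efeat <- ad_const(tape, batch$efeat)
    if (with_edge_coeff) {
      edge_coeff <- ad_node(tape, matrix(1, n_edges, 1))
      efeat <- op_rowscale(tape, efeat, edge_coeff)
    }
    E0 <- op_add_vec(tape, op_matmul(tape, efeat, bind(params$w_edge, "w_edge")),
                     bind(params$b_edge, "b_edge"))
  }
  X <- X0
  for (l in seq_len(config$num_layers)) {
    lp <- params$layers[[l]]
    pth <- function(nm) sprintf("layers/%d/%s", l, nm)
    Hn <- op_batchnorm(tape, X, bind(lp$bn_gamma, pth("bn_gamma")),
                       bind(lp$bn_beta, pth("bn_beta")),
                       params$bn_state, sprintf("l%d_pre", l), training)
    R <- op_relu(tape, Hn)
    if (!is.null(config$dilation)) {
      nb <- dilated_knn(R$v, config$dilation$k, config$dilation$d)
      src <- unlist(nb)
      dst <- rep(seq_along(nb), each = config$dilation$k)
      segs <- make_segments(dst, batch$n_nodes)
      msg <- op_add_scalar_const(tape, op_relu(tape, op_gather(tape, R, src)),
                                 MESSAGE_EPS)
    } else {
      segs <- batch$agg_segs
      if (n_edges == 0) { # isolated nodes only: aggregated message is zero
        msg <- NULL
      } else {
        msg <- op_add_scalar_const(
          tape, op_relu(tape, op_add(tape, op_gather(tape, R, batch$src), E0)),
          MESSAGE_EPS)
      }
    }
    M <- if (is.null(msg)) {
      ad_const(tape, matrix(0, batch$n_nodes, h))
    } else if (config$aggregation == "softmax") {
      op_seg_softmax_agg(tape, msg, segs, bind(lp$beta_agg, pth("beta_agg")))
    } else {
      op_seg_powermean_agg(tape, msg, segs, p = config$powermean_p)
    }
    U <- op_add(tape, R, M)
    Z1 <- op_add_vec(tape, op_matmul(tape, U, bind(lp$w1, pth("w1"))),
                     bind(lp$b1, pth("b1")))
    Z1n <- op_batchnorm(tape, Z1, bind(lp$bn2_gamma, pth("bn2_gamma")),
                        bind(lp$bn2_beta, pth("bn2_beta")),
                        params$bn_state, sprintf("l%d_mlp", l), training)
    A1 <- op_relu(tape, Z1n)
    if (training && config$dropout > 0) {
      mask <- matrix(stats::rbinom(length(A1$v), 1, 1 - config$dropout) /
                       (1 - config$dropout), nrow(A1$v), ncol(A1$v))
      A1 <- op_mul(tape, A1, ad_const(tape, mask))
    }
    Conv <- op_add_vec(tape, op_matmul(tape, A1, bind(lp$w2, pth("w2"))),
                       bind(lp$b2, pth("b2")))
    X <- op_add(tape, X, Conv)
  }
  pooled <- op_seg_pool(tape, X, batch$pool_segs, config$pooling)
  list(pooled = pooled, x0 = X0, xfinal = X, edge_coeff = edge_coeff)
}

#' Forward pass of one GCN module
#'
#' Embeds the graph's one-hot features, applies `num_layers` pre-activation
#' residual message-passing blocks, and pools nodes to one fixed-size vector
#' per graph. Deterministic in evaluation mode for fixed parameters.
#'
#' @param graph A `mol_graph` or list of them.
#' @param params A `module_params`.
#' @param config The matching [gcn_config()].
#' @param training Use batch normalization statistics and dropout (default
#'   `FALSE`: evaluation mode).
#' @return Matrix of pooled embeddings, one row per input graph.
#' @export
gcn_forward <- function(graph, params, config, training = FALSE) {
  batch <- graph_batch(graph)
  tape <- tape_new()
  out <- gcn_forward_tape(tape, batch, params, config, training = training)
  out$pooled$v
}
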