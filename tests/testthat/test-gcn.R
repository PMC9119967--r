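test_that("input embedding is a linear projection with the expected shapes", {
  cfg <- gcn_config(num_layers = 0, hidden_dim = 4)
  set.seed(1)
  params <- init_module_params(cfg)
  g <- smiles_to_graph("CCO")
  emb <- embed_inputs(g, params)
  expect_equal(dim(emb$node), c(3, 4))
  expect_equal(dim(emb$edge), c(4, 4))

  zero <- params
  zero$w_node[] <- 0; zero$b_node[] <- 0
  expect_true(all(embed_inputs(g, zero)$node == 0))

  e <- embed_inputs(smiles_to_graph("CC"), params)  # identical atoms
  expect_equal(e$node[1, ], e$node[2, ])

  one <- embed_inputs(smiles_to_graph("C"), params) # single node, no edges
  expect_equal(nrow(one$node), 1)
  expect_equal(nrow(one$edge), 0)
})

test_that("message construction follows ReLU(x_u + x_e) + eps", {
  eps <- planet:::MESSAGE_EPS
  expect_equal(message_construct(NULL, c(0, 0), c(0, 0)), rep(eps, 2))
  expect_equal(message_construct(NULL, c(-3, -1), c(1, -2)), rep(eps, 2))
  expect_equal(message_construct(NULL, c(1, 0), c(0, 1)), c(1 + eps, 1 + eps))
})

test_that("softmax aggregation recovers its limiting cases", {
  m <- matrix(c(1, 5, 3), 3, 1)
  expect_equal(aggregate_softmax(m[1, , drop = FALSE], beta = 2.5), 1)
  expect_equal(aggregate_softmax(m, beta = 0), mean(m))
  two <- matrix(c(0, 10), 2, 1)
  expect_lt(abs(aggregate_softmax(two, beta = 100) - 10), 1e-3)
  # monotone approach to the feature-wise max
  vals <- vapply(c(0, 0.1, 0.3, 1), function(b) aggregate_softmax(two, b), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_equal(aggregate_softmax(matrix(numeric(0), 0, 3)), c(0, 0, 0))
})

test_that("node update MLP composes to identity with constructed weights", {
  w1 <- matrix(c(1, -1), 1, 2); w2 <- matrix(c(1, -1), 2, 1)
  for (x in c(-2, 0.5, 3)) {
    expect_equal(node_update(x, 0.7, w1, c(0, 0), w2, 0), x + 0.7)
    expect_equal(node_update(x, 0, w1, c(0, 0), w2, 0), x)
  }
  expect_equal(node_update(0, 0, 0 * w1, c(0, 0), 0 * w2, 0), 0)
})

test_that("zeroed convolution branches make the residual stack an identity", {
  cfg <- gcn_config(num_layers = 20, hidden_dim = 8)
  set.seed(2)
  params <- init_module_params(cfg)
  for (l in seq_along(params$layers)) {
    params$layers[[l]]$w2[] <- 0
    params$layers[[l]]$b2[] <- 0
  }
  g <- smiles_to_graph("Nc1ccc2ccccc2c1")
  out <- gcn_forward(g, params, cfg)
  expect_equal(as.numeric(out), colMeans(embed_inputs(g, params)$node),
               tolerance = 1e-12)
})

test_that("a 1-D two-layer forward pass matches an independent hand trace", {
  cfg <- gcn_config(num_layers = 2, hidden_dim = 1)
  set.seed(3)
  params <- init_module_params(cfg)
  params$layers[[1]]$beta_agg <- 1.7
  params$layers[[2]]$beta_agg <- 0.4
  for (l in 1:2) {
    params$layers[[l]]$bn_gamma <- runif(1, 0.5, 1.5)
    params$layers[[l]]$bn_beta <- rnorm(1, 0, 0.3)
    params$layers[[l]]$bn2_gamma <- runif(2, 0.5, 1.5)
    params$layers[[l]]$bn2_beta <- rnorm(2, 0, 0.3)
  }
  g <- smiles_to_graph("CCO")  # 3-node path

  hand_forward <- function(g, params) {
    bn <- function(x, gamma, beta) gamma * x / sqrt(1 + 1e-5) + beta
    x <- as.numeric(g$node_features %*% params$w_node) + params$b_node
    e <- as.numeric(g$edge_features %*% params$w_edge) + params$b_edge
    for (l in 1:2) {
      lp <- params$layers[[l]]
      r <- pmax(bn(x, lp$bn_gamma, lp$bn_beta), 0)
      newx <- x
      for (v in seq_len(g$node_count)) {
        incoming <- which(g$edges[, 2] == v)
        msgs <- vapply(incoming, function(ei) {
          max(r[g$edges[ei, 1]] + e[ei], 0) + planet:::MESSAGE_EPS
        }, numeric(1))
        w <- exp(lp$beta_agg * msgs); w <- w / sum(w)
        u <- r[v] + sum(w * msgs)
        z1 <- u * as.numeric(lp$w1) + lp$b1
        a1 <- pmax(bn(z1, lp$bn2_gamma, lp$bn2_beta), 0)
        newx[v] <- x[v] + sum(a1 * as.numeric(lp$w2)) + lp$b2
      }
      x <- newx
    }
    mean(x)
  }

  expect_equal(as.numeric(gcn_forward(g, params, cfg)), hand_forward(g, params),
               tolerance = 1e-10)
})

test_that("pooled embeddings are invariant to node relabelling", {
  cfg <- gcn_config(num_layers = 4, hidden_dim = 8)
  set.seed(4)
  params <- init_module_params(cfg)
  g <- smiles_to_graph("CC(=O)Oc1ccccc1C(=O)O")
  out <- gcn_forward(g, params, cfg)
  for (r in 1:3) {
    perm <- sample(g$node_count)
    out_p <- gcn_forward(permute_graph(g, perm), params, cfg)
    expect_lt(max(abs(out - out_p)), 1e-6)
  }
})

test_that("dilated k-NN selects every d-th of the k*d nearest", {
  emb <- matrix(c(0, 1, 2, 3), 4, 1)
  expect_equal(dilated_knn(emb, k = 1, d = 3)[[1]], 4)    # farthest survivor
  nb <- dilated_knn(emb, k = 3, d = 1)
  expect_equal(sort(nb[[1]]), 2:4)                        # plain k-NN
  expect_equal(nb[[2]], c(1, 3, 4))                       # ties by node index
  expect_error(dilated_knn(emb, k = 2, d = 2), "exceeds")
})

test_that("pooling variants reduce node embeddings as stated", {
  emb <- matrix(c(0, 2, 2, 0), 2, 2, byrow = TRUE)
  expect_equal(pool_nodes(emb, "mean"), c(1, 1))
  expect_equal(pool_nodes(emb, "sum"), c(2, 2))
  expect_equal(pool_nodes(emb, "max"), c(2, 2))
  single <- matrix(c(3, -1), 1, 2)
  for (m in c("mean", "max", "sum"))
    expect_equal(pool_nodes(single, m), c(3, -1))
  expect_error(pool_nodes(matrix(numeric(0), 0, 2)), "empty")
})

test_that("a zero-depth module is pooling over input embeddings", {
  cfg <- gcn_config(num_layers = 0, hidden_dim = 6)
  set.seed(5)
  params <- init_module_params(cfg)
  g <- smiles_to_graph("c1ccncc1")
  expect_equal(as.numeric(gcn_forward(g, params, cfg)),
               colMeans(embed_inputs(g, params)$node))
})

test_that("gradients reach the first layer of a 20-layer stack", {
  cfg <- gcn_config(num_layers = 20, hidden_dim = 8)
  set.seed(6)
  fp <- init_fusion_params(cfg)
  g <- smiles_to_graph("CC(=O)Oc1ccccc1C(=O)O")
  tape <- planet:::tape_new()
  reg <- new.env()
  out <- planet:::ligand_only_forward_tape(tape, planet:::graph_batch(g), fp,
                                           registry = reg)
  grads <- planet:::tape_backward(tape, planet:::op_bce_logits(tape, out$logit, 1))
  g1 <- grads[[reg[["lm/layers/1/w1"]]]]
  expect_false(is.null(g1))
  expect_gt(sqrt(sum(g1^2)), 0)
})
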