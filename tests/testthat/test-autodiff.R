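# Finite-difference validation of the reverse-mode tape. Each check builds a
# small random computation, backpropagates, and compares every input
# gradient against central differences.

fd_check <- function(build, inputs, tol = 1e-6) {
  tape <- tape_new <- planet:::tape_new()
  nodes <- lapply(inputs, function(x) planet:::ad_node(tape, x))
  root <- build(tape, nodes)
  grads <- planet:::tape_backward(tape, root)
  eps <- 1e-6
  for (k in seq_along(inputs)) {
    g <- grads[[nodes[[k]]$id]]
    for (j in seq_len(min(length(inputs[[k]]), 5))) {
      up <- inputs; up[[k]][j] <- up[[k]][j] + eps
      dn <- inputs; dn[[k]][j] <- dn[[k]][j] - eps
      f <- function(ins) {
        tp <- planet:::tape_new()
        nd <- lapply(ins, function(x) planet:::ad_node(tp, x))
        build(tp, nd)$v[1, 1]
      }
      num <- (f(up) - f(dn)) / (2 * eps)
      expect_equal(as.numeric(g)[j], num, tolerance = tol,
                   info = sprintf("input %d entry %d", k, j))
    }
  }
}

test_that("dense ops backpropagate exact gradients", {
  set.seed(1)
  A <- matrix(rnorm(12), 3, 4); W <- matrix(rnorm(8), 4, 2)
  b <- matrix(rnorm(2), 1, 2)
  fd_check(function(tp, nd) {
    h <- planet:::op_relu(tp, planet:::op_add_vec(tp,
           planet:::op_matmul(tp, nd[[1]], nd[[2]]), nd[[3]]))
    planet:::op_sum(tp, planet:::op_mul(tp, h, h))
  }, list(A, W, b))
})

test_that("segment softmax aggregation gradients are exact (incl. beta)", {
  set.seed(2)
  M <- matrix(rnorm(10), 5, 2)
  beta <- matrix(1.3, 1, 1)
  segs <- planet:::make_segments(c(1L, 1L, 2L, 2L, 2L), 3L)
  fd_check(function(tp, nd) {
    planet:::op_sum(tp, planet:::op_mul(tp,
      planet:::op_seg_softmax_agg(tp, nd[[1]], segs, nd[[2]]),
      planet:::ad_const(tp, matrix(c(1, -2, 0.5, 1, 2, -1), 3, 2))))
  }, list(M, beta))
})

test_that("batch normalization gradients are exact in training mode", {
  set.seed(3)
  X <- matrix(rnorm(12), 4, 3)
  gamma <- matrix(runif(3, 0.5, 1.5), 1, 3)
  beta <- matrix(rnorm(3), 1, 3)
  st <- new.env()
  fd_check(function(tp, nd) {
    y <- planet:::op_batchnorm(tp, nd[[1]], nd[[2]], nd[[3]],
                               st, "k", training = TRUE)
    planet:::op_sum(tp, planet:::op_mul(tp, y, y))
  }, list(X, gamma, beta), tol = 1e-4)
})

test_that("segment pooling modes and their gradients are correct", {
  A <- matrix(c(0, 2, 2, 0, 5, 1), 3, 2, byrow = TRUE)
  segs <- planet:::make_segments(c(1L, 1L, 2L), 2L)
  tp <- planet:::tape_new()
  nd <- planet:::ad_node(tp, A)
  expect_equal(planet:::op_seg_pool(tp, nd, segs, "mean")$v,
               matrix(c(1, 1, 5, 1), 2, 2, byrow = TRUE))
  expect_equal(planet:::op_seg_pool(tp, nd, segs, "sum")$v[1, ], c(2, 2))
  expect_equal(planet:::op_seg_pool(tp, nd, segs, "max")$v[1, ], c(2, 2))
  fd_check(function(tp, nd) {
    planet:::op_sum(tp, planet:::op_mul(tp,
      planet:::op_seg_pool(tp, nd[[1]], segs, "mean"),
      planet:::ad_const(tp, matrix(c(1, 2, 3, 4), 2, 2))))
  }, list(A))
})

test_that("binary cross-entropy head matches a direct computation", {
  z <- matrix(c(2, -1, 0.5), 3, 1)
  y <- c(1, 0, 1)
  tp <- planet:::tape_new()
  nd <- planet:::ad_node(tp, z)
  loss <- planet:::op_bce_logits(tp, nd, y)
  p <- 1 / (1 + exp(-z))
  expect_equal(loss$v[1, 1], mean(-y * log(p) - (1 - y) * log(1 - p)))
  grads <- planet:::tape_backward(tp, loss)
  expect_equal(as.numeric(grads[[nd$id]]), as.numeric((p - y) / 3))
})
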