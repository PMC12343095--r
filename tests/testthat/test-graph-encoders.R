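# Graph convolution, graph attention, attentive-fingerprint encoding,
# pooling; all checked against independent dense/loop oracles.

test_that("gcn_layer matches hand arithmetic on trivial graphs", {
  # single node with self-loop only: D = 1, A^ = 1 -> identity
  H <- matrix(c(2, -3), 1)
  out <- gcn_layer(H, matrix(0, 1, 1),
                   list(W = diag(2), activation = "identity"))
  expect_equal(out, H)

  # two-node path, hand-multiplied normalization
  H2 <- diag(2)
  A2 <- matrix(c(0, 1, 1, 0), 2)
  out2 <- gcn_layer(H2, A2, list(W = diag(2), activation = "identity"))
  Ahat <- A2 + diag(2)
  D <- diag(1 / sqrt(rowSums(Ahat)))
  expect_equal(out2, D %*% Ahat %*% D %*% H2, tolerance = 1e-12)
})

test_that("gcn_layer equals the dense-matrix oracle on random graphs", {
  set.seed(101)
  for (i in 1:20) {
    g <- random_graph(sample(2:6, 1))
    W <- matrix(rnorm(3 * 2), 3, 2)
    out <- gcn_layer(g$H, g$A, list(W = W, activation = "relu"))
    Ahat <- g$A + diag(g$n)
    D <- diag(1 / sqrt(rowSums(Ahat)), g$n)
    expect_equal(out, pmax(D %*% Ahat %*% D %*% g$H %*% W, 0),
                 tolerance = 1e-6)
  }
})

test_that("gcn_layer rejects inconsistent shapes", {
  expect_error(gcn_layer(matrix(0, 2, 3), matrix(0, 3, 3),
                         list(W = diag(3))), "dimension error")
  expect_error(gcn_layer(matrix(0, 2, 3), matrix(0, 2, 2),
                         list(W = diag(2))), "dimension error")
})

test_that("attention coefficients form a softmax over each neighborhood", {
  set.seed(7)
  # node with exactly one neighbor and no self: impossible (self-loops are
  # added), so check the defining softmax properties instead
  H <- matrix(rnorm(8), 4, 2)
  params <- list(W = matrix(rnorm(4), 2, 2), a = rnorm(4))
  alpha <- gat_attention(H, rbind(c(1, 2), c(2, 3)), params)
  expect_equal(rowSums(alpha), rep(1, 4), tolerance = 1e-6)
  expect_true(all(alpha >= 0))
  # node 4 is isolated: all mass on its self-loop
  expect_equal(alpha[4, 4], 1)

  # two neighbors with identical features share the mass equally
  Hs <- rbind(c(1, 0), c(0.5, 2), c(0.5, 2))
  as <- gat_attention(Hs, rbind(c(1, 2), c(1, 3)), params)
  expect_equal(as[1, 2], as[1, 3], tolerance = 1e-9)
})

test_that("attention reproduces scalar softmax arithmetic on set logits", {
  # 1-d features, W = 1, a = (0, 1): logit(u -> w) = leakyrelu(h_w).
  # Node 1 (h = 0) attends over {self: 0, node 2: 1, node 3: 2}.
  H <- matrix(c(0, 1, 2), 3)
  alpha <- gat_attention(H, rbind(c(1, 2), c(1, 3)),
                         list(W = matrix(1), a = c(0, 1)))
  expect_equal(alpha[1, 3] / alpha[1, 2], exp(2) / exp(1), tolerance = 1e-9)
  # and softmax(1, 2) itself on the renormalized pair
  pair <- c(alpha[1, 2], alpha[1, 3]) / (alpha[1, 2] + alpha[1, 3])
  expect_equal(pair, c(0.2689414, 0.7310586), tolerance = 1e-6)
})

test_that("gat_layer equals the per-node loop oracle on random graphs", {
  set.seed(202)
  for (i in 1:20) {
    g <- random_graph(sample(2:6, 1))
    W <- matrix(rnorm(6), 3, 2)
    a <- rnorm(4)
    out <- gat_layer(g$H, g$edges,
                     list(heads = list(list(W = W, a = a)),
                          combine = "concat", activation = "relu"))
    expect_equal(out, gat_oracle(g$H, g$edges, W, a,
                                 act = function(x) pmax(x, 0)),
                 tolerance = 1e-6)
  }
})

test_that("gat_layer trivial cases: single node and uniform features", {
  W <- matrix(c(1, 0, 1, 1), 2)
  out <- gat_layer(matrix(c(3, 1), 1), matrix(integer(0), 0, 2),
                   list(heads = list(list(W = W, a = rep(0.3, 4))),
                        combine = "concat", activation = "identity"))
  expect_equal(out, matrix(c(3, 1), 1) %*% W)

  Hu <- matrix(1, 4, 2)
  ou <- gat_layer(Hu, rbind(c(1, 2), c(3, 4), c(2, 3)),
                  list(heads = list(list(W = W, a = rnorm(4)))))
  expect_equal(max(apply(ou, 2, function(x) diff(range(x)))), 0,
               tolerance = 1e-9)
})

test_that("multi-head outputs concatenate (hidden) or average (final)", {
  set.seed(5)
  g <- random_graph(4)
  heads <- list(list(W = matrix(rnorm(6), 3, 2), a = rnorm(4)),
                list(W = matrix(rnorm(6), 3, 2), a = rnorm(4)))
  cc <- gat_layer(g$H, g$edges, list(heads = heads, combine = "concat",
                                     activation = "identity"))
  av <- gat_layer(g$H, g$edges, list(heads = heads, combine = "mean",
                                     activation = "identity"))
  expect_equal(ncol(cc), 4L)
  expect_equal(av, (cc[, 1:2] + cc[, 3:4]) / 2, tolerance = 1e-9)
})

test_that("attentive-fingerprint encoding matches a step-by-step oracle", {
  set.seed(31)
  d <- 2L
  params <- list(
    W_in = matrix(rnorm(6), 3, d), b_in = rep(0.1, d),
    steps = list(list(
      W = matrix(rnorm(4), d, d), a = rnorm(2 * d),
      gru = list(Wz = matrix(rnorm(4), d, d), Uz = matrix(rnorm(4), d, d),
                 bz = rep(0, d),
                 Wr = matrix(rnorm(4), d, d), Ur = matrix(rnorm(4), d, d),
                 br = rep(0, d),
                 Wh = matrix(rnorm(4), d, d), Uh = matrix(rnorm(4), d, d),
                 bh = rep(0, d))
    ))
  )
  graph2 <- list(features = matrix(rnorm(6), 2, 3), edges = rbind(c(1, 2)))
  enc <- attfp_encode(graph2, params)

  # independent scalar unroll of the same equations
  lrelu <- function(x) ifelse(x > 0, x, 0.2 * x)
  sig <- function(x) 1 / (1 + exp(-x))
  H0 <- lrelu(graph2$features %*% params$W_in +
                matrix(params$b_in, 2, d, byrow = TRUE))
  sp <- params$steps[[1]]
  Wh <- H0 %*% sp$W
  a1 <- sp$a[1:d]; a2 <- sp$a[(d + 1):(2 * d)]
  Hn <- matrix(0, 2, d)
  for (u in 1:2) {
    nbrs <- c(u, setdiff(1:2, u))
    e <- sapply(nbrs, function(w) lrelu(sum(a1 * Wh[u, ]) + sum(a2 * Wh[w, ])))
    al <- exp(e - max(e)); al <- al / sum(al)
    m <- colSums(al * Wh[nbrs, , drop = FALSE])
    z <- sig(m %*% sp$gru$Wz + H0[u, ] %*% sp$gru$Uz)
    r <- sig(m %*% sp$gru$Wr + H0[u, ] %*% sp$gru$Ur)
    ht <- tanh(m %*% sp$gru$Wh + (r * H0[u, ]) %*% sp$gru$Uh)
    Hn[u, ] <- (1 - z) * H0[u, ] + z * ht
  }
  expect_equal(enc$h_G, matrix(colSums(Hn), 1), tolerance = 1e-9)
})

test_that("attentive-fingerprint readout is node-order invariant", {
  set.seed(32)
  d <- 3L
  mk_gru <- function() list(Wz = matrix(rnorm(9), d, d),
                            Uz = matrix(rnorm(9), d, d), bz = rep(0, d),
                            Wr = matrix(rnorm(9), d, d),
                            Ur = matrix(rnorm(9), d, d), br = rep(0, d),
                            Wh = matrix(rnorm(9), d, d),
                            Uh = matrix(rnorm(9), d, d), bh = rep(0, d))
  params <- list(W_in = matrix(rnorm(9), 3, d), b_in = rep(0, d),
                 steps = list(list(W = matrix(rnorm(9), d, d),
                                   a = rnorm(2 * d), gru = mk_gru()),
                              list(W = matrix(rnorm(9), d, d),
                                   a = rnorm(2 * d), gru = mk_gru())))
  X <- matrix(rnorm(9), 3, 3)
  g1 <- list(features = X, edges = rbind(c(1, 2), c(2, 3)))
  perm <- c(3, 1, 2)  # relabel nodes
  inv <- order(perm)
  g2 <- list(features = X[perm, ],
             edges = cbind(inv[c(1, 2)], inv[c(2, 3)]))
  e1 <- attfp_encode(g1, params)
  e2 <- attfp_encode(g2, params)
  expect_equal(e1$h_G, e2$h_G, tolerance = 1e-9)

  # single node: h_G equals that node's final GRU state
  g0 <- list(features = X[1, , drop = FALSE], edges = matrix(0L, 0, 2))
  e0 <- attfp_encode(g0, params)
  expect_equal(e0$h_G, e0$H, tolerance = 1e-12)
})

test_that("global pooling computes mean, sum and max; empty graphs error", {
  H <- rbind(c(1, 3), c(3, 1))
  expect_equal(global_pool(H, "mean"), matrix(c(2, 2), 1))
  expect_equal(global_pool(H, "sum"), matrix(c(4, 4), 1))
  expect_equal(global_pool(H, "max"), matrix(c(3, 3), 1))
  expect_equal(global_pool(H[2:1, ], "mean"), global_pool(H, "mean"))
  h1 <- matrix(c(5, 7), 1)
  for (m in c("mean", "sum", "max")) expect_equal(global_pool(h1, m), h1)
  expect_error(global_pool(matrix(0, 0, 2)), "empty")
})

test_that("zero-weight layers with identity activation annihilate input", {
  set.seed(77)
  g <- random_graph(4)
  Z <- matrix(0, 3, 2)
  expect_equal(gcn_layer(g$H, g$A, list(W = Z, activation = "identity")),
               matrix(0, 4, 2))
  expect_equal(gat_layer(g$H, g$edges,
                         list(heads = list(list(W = Z, a = rep(0, 4))),
                              activation = "identity", combine = "concat")),
               matrix(0, 4, 2))
})

test_that("node relabeling permutes encoder outputs consistently", {
  set.seed(88)
  g <- random_graph(5)
  W <- matrix(rnorm(6), 3, 2)
  a <- rnorm(4)
  perm <- sample(5)
  inv <- order(perm)
  Hp <- g$H[perm, ]
  edges_p <- cbind(inv[g$edges[, 1]], inv[g$edges[, 2]])
  Ap <- g$A[perm, perm]
  o1 <- gcn_layer(g$H, g$A, list(W = W))
  o1p <- gcn_layer(Hp, Ap, list(W = W))
  expect_equal(o1p, o1[perm, ], tolerance = 1e-9)
  o2 <- gat_layer(g$H, g$edges, list(heads = list(list(W = W, a = a))))
  o2p <- gat_layer(Hp, edges_p, list(heads = list(list(W = W, a = a))))
  expect_equal(o2p, o2[perm, ], tolerance = 1e-9)
})
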