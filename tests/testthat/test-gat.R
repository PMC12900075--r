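# Graph attention layers against dense masked-softmax and loop oracles.

random_graph <- function(n, k, seed) {
  set.seed(seed)
  knn_spatial_graph(matrix(runif(2 * n), n, 2), k = k)
}

test_that("a single-neighbour node gets attention 1 on its only edge", {
  # no self-loops, so each node attends to exactly its one neighbour
  adj <- rbind(c(0, 1), c(1, 0))
  set.seed(1)
  par <- init_gat_layer(3, 2)
  x <- matrix(rnorm(6), 2, 3)
  att <- gat_attention(x, adj, par, self_loops = FALSE)
  expect_equal(unname(att$alpha[, 1]), c(1, 1))
})

test_that("zero attention vectors give uniform weights over the neighbourhood", {
  g <- random_graph(12, 3, seed = 2)
  set.seed(3)
  par <- init_gat_layer(4, 3)
  par$a_src[[1]][] <- 0
  par$a_dst[[1]][] <- 0
  x <- matrix(rnorm(48), 12, 4)
  att <- gat_attention(x, g, par)            # self-loops: 4 neighbours each
  expect_equal(unname(att$alpha[, 1]), rep(0.25, length(att$i)))
})

test_that("attention matches the dense masked-softmax oracle (K = 1 and 2)", {
  for (K in 1:2) {
    g <- random_graph(8, 3, seed = 10 + K)
    set.seed(20 + K)
    par <- init_gat_layer(5, 4, heads = K)
    x <- matrix(rnorm(40), 8, 5)
    adj_sl <- as.matrix(g$adjacency) + diag(8)
    ref <- oracle_gat_attention(x, adj_sl, par)
    att <- gat_attention(x, g, par)
    for (k in seq_len(K))
      expect_equal(alpha_to_dense(att, k), ref[[k]], tolerance = 1e-12)
  }
})

test_that("attention rows sum to one per head and node", {
  g <- random_graph(40, 6, seed = 30)
  set.seed(31)
  par <- init_gat_layer(7, 3, heads = 2)
  x <- matrix(rnorm(280), 40, 7)
  att <- gat_attention(x, g, par)
  for (k in 1:2) {
    sums <- tapply(att$alpha[, k], att$i, sum)
    expect_true(all(abs(sums - 1) < 1e-6))
  }
  expect_true(all(att$alpha >= 0))
})

test_that("layer forward equals the dense and triple-loop oracles", {
  g <- random_graph(15, 4, seed = 40)
  set.seed(41)
  par <- init_gat_layer(6, 3, heads = 2)
  x <- matrix(rnorm(90), 15, 6)
  adj_sl <- as.matrix(g$adjacency) + diag(15)
  H <- gat_layer(x, g, par)
  expect_equal(H, oracle_gat_layer(x, adj_sl, par), tolerance = 1e-10)
  expect_equal(H, oracle_gat_layer_loops(x, adj_sl, par), tolerance = 1e-10)
})

test_that("uniform aggregation with identity weights averages the neighbourhood", {
  # star graph: node 1 is the hub
  n <- 6
  adj <- matrix(0, n, n)
  adj[1, 2:n] <- 1
  adj[2:n, 1] <- 1
  set.seed(50)
  par <- init_gat_layer(3, 3)
  par$W[[1]] <- diag(3)
  x <- matrix(rnorm(n * 3), n, 3)
  H <- gat_layer(x, adj, par, mode = "uniform")   # self-loops included
  expect_equal(H[1, ], colMeans(x), tolerance = 1e-12)
  expect_equal(H[2, ], colMeans(x[c(1, 2), ]), tolerance = 1e-12)
})

test_that("two identical heads produce equal concatenated halves", {
  g <- random_graph(10, 3, seed = 60)
  set.seed(61)
  par <- init_gat_layer(4, 3, heads = 2)
  par$W[[2]] <- par$W[[1]]
  par$a_src[[2]] <- par$a_src[[1]]
  par$a_dst[[2]] <- par$a_dst[[1]]
  x <- matrix(rnorm(40), 10, 4)
  H <- gat_layer(x, g, par)
  expect_equal(H[, 1:3], H[, 4:6], tolerance = 1e-12)
})

test_that("width mismatches and isolated nodes raise informative errors", {
  g <- random_graph(6, 2, seed = 70)
  set.seed(71)
  par <- init_gat_layer(4, 3)
  expect_error(gat_layer(matrix(0, 6, 5), g, par), "width mismatch")
  adj <- matrix(0, 3, 3)
  adj[1, 2] <- adj[2, 1] <- 1                     # node 3 isolated
  expect_error(gat_attention(matrix(rnorm(12), 3, 4), adj, par,
                             self_loops = FALSE),
               "isolated node")
})

test_that("layer update applies the residual projection as documented", {
  set.seed(80)
  par <- init_gat_layer(5, 3, act = "elu", use_ln = FALSE)  # widths differ
  h <- matrix(rnorm(12), 4, 3)
  x_prev <- matrix(rnorm(20), 4, 5)
  out <- gat_layer_update(h, x_prev, par)
  elu <- function(z) ifelse(z > 0, z, exp(z) - 1)
  expect_equal(out, elu(h) + x_prev %*% par$W_res, tolerance = 1e-12)
  expect_equal(ncol(out), 3L)
  # equal widths: no projection, identity residual
  par2 <- init_gat_layer(3, 3, act = "identity", use_ln = FALSE)
  expect_null(par2$W_res)
  expect_equal(gat_layer_update(h, h, par2), 2 * h)
})

test_that("layer update is deterministic without dropout and stochastic with it", {
  set.seed(90)
  par <- init_gat_layer(4, 4)
  h <- matrix(rnorm(40), 10, 4)
  xp <- matrix(rnorm(40), 10, 4)
  expect_identical(gat_layer_update(h, xp, par),
                   gat_layer_update(h, xp, par))
  set.seed(1)
  a <- gat_layer_update(h, xp, par, dropout = 0.5, training = TRUE)
  b <- gat_layer_update(h, xp, par, dropout = 0.5, training = TRUE)
  expect_false(identical(a, b))
})

test_that("a one-layer stack composes gat_layer and gat_layer_update", {
  g <- random_graph(9, 3, seed = 100)
  set.seed(101)
  stack <- init_gat_stack(c(5, 3), heads = 1, dropout = 0)
  x <- matrix(rnorm(45), 9, 5)
  par <- stack$layers[[1]]
  expect_equal(gat_encode(x, g, stack),
               gat_layer_update(gat_layer(x, g, par), x, par),
               tolerance = 1e-12)
})

test_that("encoding is permutation-equivariant", {
  n <- 30
  g <- random_graph(n, 4, seed = 110)
  set.seed(111)
  stack <- init_gat_stack(c(6, 8, 4), heads = 1, dropout = 0)
  x <- matrix(rnorm(n * 6), n, 6)
  z <- gat_encode(x, g, stack)
  perm <- sample(n)
  adj <- as.matrix(g$adjacency)[perm, perm]
  zp <- gat_encode(x[perm, ], adj, stack)
  expect_equal(zp, z[perm, ], tolerance = 1e-8)
})

test_that("a self-loop-only graph with identity weights reproduces the input", {
  set.seed(120)
  par <- init_gat_layer(4, 4)
  par$W[[1]] <- diag(4)
  x <- matrix(rnorm(28), 7, 4)
  adj <- matrix(0, 7, 7)    # self-loops added internally: N(i) = {i}
  expect_equal(gat_layer(x, adj, par), x, tolerance = 1e-12)
})

test_that("stacks flag NaN intermediates with the layer index", {
  g <- random_graph(5, 2, seed = 130)
  set.seed(131)
  stack <- init_gat_stack(c(3, 2), dropout = 0)
  x <- matrix(rnorm(15), 5, 3)
  x[1, 1] <- Inf            # poisons the first aggregation
  expect_error(gat_encode(x, g, stack), "non-finite")
})

test_that("decoder stacks mirror encoder widths and reduce loss when trained", {
  expect_equal(init_gat_stack(c(64, 256, 10), role = "decoder")$widths,
               c(64L, 256L, 10L))
  # a trained toy autoencoder beats its own initialization
  sim <- simulate_spatial_pair(n_spots = 100, n_domains = 2, f1 = 10, f2 = 6,
                               seed = 8)
  fit <- gatfuse(sim, k_feat = 5, k_spat = 5, hidden = 16, latent = 8,
                 epochs = 60, seed = 0)
  expect_lt(fit$log$total[nrow(fit$log)], fit$log$total[1])
})
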