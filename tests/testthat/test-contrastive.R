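# Cross-modal contrastive loss and temperature annealing.

test_that("l2_normalize follows the 3-4-5 triangle and is idempotent", {
  expect_equal(drop(l2_normalize(matrix(c(3, 4), 1, 2))), c(0.6, 0.8))
  set.seed(1)
  h <- matrix(rnorm(20 * 8), 20, 8)
  hn <- l2_normalize(h)
  expect_equal(unname(sqrt(rowSums(hn^2))), rep(1, 20), tolerance = 1e-6)
  expect_equal(l2_normalize(hn), hn, tolerance = 1e-12)
  h[3, ] <- 0
  expect_error(l2_normalize(h), "degenerate.*3")
})

test_that("positive similarity is the per-spot dot product", {
  set.seed(2)
  a <- l2_normalize(matrix(rnorm(24), 6, 4))
  expect_equal(positive_similarity(a, a), rep(1, 6), tolerance = 1e-12)
  b <- l2_normalize(matrix(rnorm(24), 6, 4))
  sp <- positive_similarity(a, b)
  expect_equal(sp, vapply(1:6, function(i) sum(a[i, ] * b[i, ]), numeric(1)))
  expect_true(all(abs(sp) <= 1 + 1e-12))
  # orthogonal rows give zero
  e1 <- matrix(c(1, 0), 1, 2)
  e2 <- matrix(c(0, 1), 1, 2)
  expect_equal(positive_similarity(e1, e2), 0)
})

test_that("negative similarity sums the four modality combinations", {
  u <- c(1, 0, 0)
  h <- rbind(u, u)
  expect_equal(negative_similarity(h, h, 1, 2), 4)
  # both modalities pairwise orthogonal across spots -> 0
  a <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  b <- rbind(c(0, 0, 1, 0), c(0, 0, 0, 1))
  expect_equal(negative_similarity(a, b, 1, 2), 0)
  set.seed(3)
  an <- l2_normalize(matrix(rnorm(50), 10, 5))
  bn <- l2_normalize(matrix(rnorm(50), 10, 5))
  for (i in c(1, 4)) for (j in c(2, 9)) {
    expect_equal(negative_similarity(an, bn, i, j),
                 sum(an[i, ] * bn[j, ]) + sum(bn[i, ] * an[j, ]) +
                   sum(bn[i, ] * bn[j, ]) + sum(an[i, ] * an[j, ]),
                 tolerance = 1e-12)
  }
  expect_error(negative_similarity(an, bn, 2, 2), "must differ")
})

test_that("contrastive loss identities hold exactly", {
  # single spot: no negatives, loss 0
  expect_identical(contrastive_loss(matrix(1:3, 1), matrix(4:6, 1)), 0)
  # two spots sharing one unit embedding in both modalities, tau = 1
  u <- c(1, 0)
  h <- rbind(u, u)
  cfg <- contrastive_config(tau = 1)
  expect_equal(contrastive_loss(h, h, cfg), log(1 + exp(3)), tolerance = 1e-6)
})

test_that("vectorized loss equals the per-spot loop oracle", {
  set.seed(4)
  for (n in c(5, 17, 30)) {
    h1 <- matrix(rnorm(n * 6), n, 6)
    h2 <- matrix(rnorm(n * 6), n, 6)
    cfg <- contrastive_config(tau = 0.5)
    expect_equal(contrastive_loss(h1, h2, cfg),
                 oracle_contrastive(h1, h2, 0.5), tolerance = 1e-5)
  }
})

test_that("the loss is invariant to a common orthogonal rotation", {
  set.seed(5)
  h1 <- matrix(rnorm(12 * 6), 12, 6)
  h2 <- matrix(rnorm(12 * 6), 12, 6)
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  cfg <- contrastive_config(tau = 0.7)
  expect_equal(contrastive_loss(h1 %*% Q, h2 %*% Q, cfg),
               contrastive_loss(h1, h2, cfg), tolerance = 1e-5)
})

test_that("raising the positive similarity with negatives fixed lowers the loss", {
  # h1_i = e_{2i-1}, h2_i = cos(theta) e_{2i-1} + sin(theta) e_{2i}: every
  # cross- and within-modality similarity between different spots is 0, so
  # only s+ = cos(theta) moves as theta shrinks
  emb <- function(theta) {
    n <- 3
    h1 <- matrix(0, n, 2 * n)
    h2 <- matrix(0, n, 2 * n)
    for (i in seq_len(n)) {
      h1[i, 2 * i - 1] <- 1
      h2[i, 2 * i - 1] <- cos(theta)
      h2[i, 2 * i] <- sin(theta)
    }
    list(h1 = h1, h2 = h2)
  }
  losses <- vapply(c(0.9, 0.6, 0.3), function(th) {
    e <- emb(th)
    contrastive_loss(e$h1, e$h2)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("analytic gradients match central finite differences", {
  set.seed(7)
  n <- 4; d <- 3
  h1 <- matrix(rnorm(n * d), n, d)
  h2 <- matrix(rnorm(n * d), n, d)
  cfg <- contrastive_config(tau = 0.6)
  g <- contrastive_loss(h1, h2, cfg, grad = TRUE)
  eps <- 1e-5
  for (idx in seq_len(n * d)) {
    for (side in 1:2) {
      hp <- if (side == 1) h1 else h2
      hp[idx] <- hp[idx] + eps
      lp <- contrastive_loss(if (side == 1) hp else h1,
                             if (side == 2) hp else h2, cfg)
      hm <- if (side == 1) h1 else h2
      hm[idx] <- hm[idx] - eps
      lm <- contrastive_loss(if (side == 1) hm else h1,
                             if (side == 2) hm else h2, cfg)
      fd <- (lp - lm) / (2 * eps)
      an <- if (side == 1) g$dh1[idx] else g$dh2[idx]
      expect_equal(an, fd, tolerance = 1e-4)
    }
  }
  # temperature gradient
  dtau_fd <- (contrastive_loss(h1, h2, contrastive_config(tau = 0.6 + eps)) -
              contrastive_loss(h1, h2, contrastive_config(tau = 0.6 - eps))) /
    (2 * eps)
  expect_equal(g$dtau, dtau_fd, tolerance = 1e-4)
})

test_that("sampled negatives restrict the negative set reproducibly", {
  set.seed(8)
  h1 <- matrix(rnorm(20 * 5), 20, 5)
  h2 <- matrix(rnorm(20 * 5), 20, 5)
  cfg <- contrastive_config(neg_strategy = "sampled", n_neg = 3)
  set.seed(123); l1 <- contrastive_loss(h1, h2, cfg)
  set.seed(123); l2 <- contrastive_loss(h1, h2, cfg)
  expect_identical(l1, l2)
  expect_true(is.finite(l1))
  expect_error(contrastive_config(neg_strategy = "sampled"), "n_neg")
})

test_that("temperature annealing follows the printed schedule with a floor", {
  st <- list(tau = 0.5, step = 0L, anneal_factor = 0.9, anneal_every = 100L,
             tau_floor = 1e-3)
  for (s in 1:300) {
    st$step <- s
    st <- anneal_temperature(st)
  }
  expect_equal(st$tau, 0.5 * 0.9^3)   # = 0.3645
  # factor 1 leaves tau constant
  st1 <- list(tau = 0.25, step = 100L, anneal_factor = 1, anneal_every = 100L,
              tau_floor = 1e-3)
  expect_equal(anneal_temperature(st1)$tau, 0.25)
  # floor binds
  stf <- list(tau = 1e-3, step = 100L, anneal_factor = 0.5,
              anneal_every = 100L, tau_floor = 1e-3)
  expect_equal(anneal_temperature(stf)$tau, 1e-3)
  # non-multiples of the schedule do not anneal
  st2 <- list(tau = 0.5, step = 99L, anneal_factor = 0.9, anneal_every = 100L,
              tau_floor = 1e-3)
  expect_equal(anneal_temperature(st2)$tau, 0.5)
})
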