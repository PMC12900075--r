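# Independent reference ("oracle") implementations used across the tests.
# Every oracle is written naively -- dense matrices, explicit loops -- so it
# shares no code path with the package implementation it checks.

# ---- KNN graphs ------------------------------------------------------------

# row-wise top-k of a dense score matrix, self excluded; ties -> lowest index
oracle_topk <- function(score, k) {
  n <- nrow(score)
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- score[i, ]
    s[i] <- -Inf
    nb <- order(-s)[seq_len(k)]  # stable sort: equal scores keep index order
    adj[i, nb] <- 1
  }
  adj
}

oracle_pearson <- function(x) stats::cor(t(x))

oracle_cosine <- function(x) {
  nr <- sqrt(rowSums(x^2))
  tcrossprod(x / nr)
}

oracle_distance <- function(coords) as.matrix(stats::dist(coords))

# ---- GAT layers ------------------------------------------------------------

leaky_ref <- function(z) ifelse(z > 0, z, 0.2 * z)

# dense masked-softmax attention; adj must already contain any self-loops.
# Returns a list of dense N x N alpha matrices, one per head.
oracle_gat_attention <- function(x, adj, params) {
  n <- nrow(x)
  lapply(seq_len(params$heads), function(k) {
    P <- x %*% params$W[[k]]
    s <- drop(P %*% params$a_src[[k]])
    tt <- drop(P %*% params$a_dst[[k]])
    E <- leaky_ref(outer(s, rep(1, n)) + outer(rep(1, n), tt))
    E[adj == 0] <- -Inf
    A <- matrix(0, n, n)
    for (i in seq_len(n)) {
      m <- max(E[i, ])
      e <- exp(E[i, ] - m)
      e[adj[i, ] == 0] <- 0
      A[i, ] <- e / sum(e)
    }
    A
  })
}

# dense aggregation using the oracle attention; multi-head concatenated
oracle_gat_layer <- function(x, adj, params) {
  As <- oracle_gat_attention(x, adj, params)
  do.call(cbind, lapply(seq_len(params$heads), function(k)
    As[[k]] %*% (x %*% params$W[[k]])))
}

# triple-loop aggregation (over nodes i, neighbours j, heads k)
oracle_gat_layer_loops <- function(x, adj, params) {
  As <- oracle_gat_attention(x, adj, params)
  n <- nrow(x)
  out <- matrix(0, n, params$heads * params$f_head)
  for (k in seq_len(params$heads)) {
    P <- x %*% params$W[[k]]
    cols <- ((k - 1L) * params$f_head + 1L):(k * params$f_head)
    for (i in seq_len(n)) {
      acc <- numeric(params$f_head)
      for (j in seq_len(n)) {
        if (adj[i, j] != 0) acc <- acc + As[[k]][i, j] * P[j, ]
      }
      out[i, cols] <- acc
    }
  }
  out
}

# convert the package's edge-list attention output to a dense per-head matrix
alpha_to_dense <- function(att, head = 1L) {
  A <- matrix(0, att$n, att$n)
  A[cbind(att$i, att$j)] <- att$alpha[, head]
  A
}

# ---- fusion ----------------------------------------------------------------

# explicit per-spot tanh / softmax / weighted-sum loop
oracle_fuse <- function(z_list, params) {
  n <- nrow(z_list[[1]])
  D <- ncol(z_list[[1]])
  m <- length(z_list)
  alpha <- matrix(0, n, m)
  zf <- matrix(0, n, D)
  for (i in seq_len(n)) {
    logits <- vapply(z_list, function(z)
      sum(tanh(drop(z[i, ] %*% params$W)) * params$u), numeric(1))
    e <- exp(logits - max(logits))
    a <- e / sum(e)
    alpha[i, ] <- a
    for (v in seq_len(m)) zf[i, ] <- zf[i, ] + a[v] * z_list[[v]][i, ]
  }
  list(alpha = alpha, z = zf)
}

# ---- contrastive loss ------------------------------------------------------

# per-spot scalar loop over all-other-spot negatives (four-term similarity)
oracle_contrastive <- function(h1, h2, tau) {
  A <- h1 / sqrt(rowSums(h1^2))
  B <- h2 / sqrt(rowSums(h2^2))
  n <- nrow(A)
  if (n == 1L) return(0)
  total <- 0
  for (i in seq_len(n)) {
    sp <- sum(A[i, ] * B[i, ])
    sn <- vapply(setdiff(seq_len(n), i), function(j)
      sum(A[i, ] * B[j, ]) + sum(B[i, ] * A[j, ]) +
        sum(B[i, ] * B[j, ]) + sum(A[i, ] * A[j, ]),
      numeric(1))
    total <- total - log(exp(sp / tau) / (exp(sp / tau) + sum(exp(sn / tau))))
  }
  total / n
}

# ---- clustering metrics ----------------------------------------------------

# contingency-table implementation written independently (entropies from
# proportions, expected MI through dhyper)
oracle_metrics <- function(pred, truth) {
  ct <- unclass(table(truth, pred))
  N <- sum(ct)
  a <- rowSums(ct)
  b <- colSums(ct)
  H <- function(cnt) {
    p <- cnt[cnt > 0] / N
    -sum(p * log(p))
  }
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    if (ct[i, j] > 0)
      mi <- mi + ct[i, j] / N * log((ct[i, j] / N) / ((a[i] / N) * (b[j] / N)))
  }
  hom <- if (H(a) == 0) 1 else mi / H(a)
  comp <- if (H(b) == 0) 1 else mi / H(b)
  v <- if (hom + comp == 0) 0 else 2 * hom * comp / (hom + comp)
  nmi <- if (H(a) + H(b) == 0) 1 else mi / ((H(a) + H(b)) / 2)
  emi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    lo <- max(1, a[i] + b[j] - N)
    hi <- min(a[i], b[j])
    if (lo > hi) next
    for (nij in lo:hi) {
      pr <- stats::dhyper(nij, b[j], N - b[j], a[i])
      emi <- emi + pr * nij / N * log(N * nij / (a[i] * b[j]))
    }
  }
  den <- (H(a) + H(b)) / 2 - emi
  ami <- if (abs(den) < 1e-14) {
    if (abs(mi - emi) < 1e-14) 1 else 0
  } else (mi - emi) / den
  ch2 <- function(x) sum(x * (x - 1) / 2)
  expct <- ch2(a) * ch2(b) / ch2(N)
  mx <- (ch2(a) + ch2(b)) / 2
  ari <- if (mx == expct) 1 else (ch2(ct) - expct) / (mx - expct)
  c(homogeneity = unname(hom), mutual_info = unname(mi),
    v_measure = unname(v), ami = unname(ami), nmi = unname(nmi),
    ari = unname(ari))
}

# within-domain fraction of directed edges of an adjacency
within_domain_fraction <- function(adj, labels) {
  tm <- Matrix::summary(methods::as(adj, "TsparseMatrix"))
  mean(labels[tm$i] == labels[tm$j])
}

# ---- shared end-to-end benchmark fits --------------------------------------
# The default-benchmark fits are expensive (~1 min each) and several
# acceptance criteria score the same runs, so they are computed once per
# test session and cached.

.bench_cache <- new.env(parent = emptyenv())

bench_pair <- function(seed) simulate_spatial_pair(seed = seed)

# one benchmark run: simulate with `seed`, fit the given variant with the
# same seed, return the embedding plus the loss trajectory endpoints
bench_run <- function(variant, seed) {
  pair <- bench_pair(seed)
  fit <- switch(variant,
    full = gatfuse(pair, seed = seed),
    no_cl = gatfuse(pair, lambda = c(1, 1, 0), seed = seed),
    no_gat = gatfuse(pair, attention = "uniform", seed = seed))
  list(embedding = fit$embedding,
       labels = pair$labels,
       first_total = fit$log$total[1L],
       last_total = fit$log$total[nrow(fit$log)],
       diverged = fit$diverged)
}

bench_runs <- function(variant, seeds = 0:4) {
  key <- paste0(variant, "_runs")
  if (is.null(.bench_cache[[key]])) {
    .bench_cache[[key]] <- lapply(seeds, function(s) bench_run(variant, s))
  }
  .bench_cache[[key]]
}

# ARI at k = 4 of each cached run (clustering seed = fit seed)
bench_ari <- function(variant, seeds = 0:4) {
  runs <- bench_runs(variant, seeds)
  vapply(seq_along(runs), function(i) {
    lab <- cluster_embeddings(runs[[i]]$embedding, 4L, seed = seeds[i])
    unname(cluster_metrics(lab, runs[[i]]$labels)["ari"])
  }, numeric(1))
}
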