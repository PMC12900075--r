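# Clustering of the fused embedding and the six-metric supervised
# evaluation protocol (homogeneity, mutual information, V-measure, AMI,
# NMI, ARI), plus the cluster-count sweep.

#' Cluster an embedding into spatial domains
#'
#' Default method: k-means on the embedding with 10 restarts (within-cluster
#' variance minimisation), deterministic given `seed` and always returning
#' exactly `n_clusters` non-empty groups. An alternative graph-community
#' mode builds a KNN graph on the embedding and runs Louvain community
#' detection, bisecting the resolution to reach the target cluster count
#' (requires the igraph package).
#'
#' @param h embedding matrix (N x D).
#' @param n_clusters number of clusters (2 <= n_clusters <= N).
#' @param seed integer seed.
#' @param method `"kmeans"` (default) or `"graph"`.
#' @param knn neighbours for the graph-community mode.
#' @return Integer vector of cluster labels (1-based), length N.
#' @export
cluster_embeddings <- function(h, n_clusters, seed = 0L,
                               method = c("kmeans", "graph"), knn = 15L) {
  method <- match.arg(method)
  h <- as.matrix(h)
  n <- nrow(h)
  if (n_clusters > n) stop("n_clusters (", n_clusters,
                           ") exceeds the number of spots (", n, ")")
  if (n_clusters < 1) stop("n_clusters must be positive")
  if (n_clusters == n) return(seq_len(n))
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  if (method == "kmeans") {
    for (attempt in 1:5) {
      km <- tryCatch(
        stats::kmeans(h, centers = n_clusters, nstart = 10L, iter.max = 100L),
        error = function(e) NULL)
      if (!is.null(km) && length(unique(km$cluster)) == n_clusters)
        return(unname(km$cluster))
    }
    stop("k-means failed to produce ", n_clusters, " non-empty clusters")
  }
  .graph_cluster(h, n_clusters, knn)
}

.graph_cluster <- function(h, n_clusters, knn) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("graph-community clustering requires the igraph package")
  n <- nrow(h)
  knn <- min(knn, n - 1L)
  d <- as.matrix(stats::dist(h))
  diag(d) <- Inf
  edges <- integer(0)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[seq_len(knn)]
    edges <- c(edges, rbind(i, nb))
  }
  g <- igraph::simplify(igraph::make_graph(edges, n = n, directed = FALSE))
  lo <- 1e-3; hi <- 10
  best <- NULL
  for (it in 1:30) {
    mid <- sqrt(lo * hi)
    cl <- igraph::cluster_louvain(g, resolution = mid)
    k <- length(unique(igraph::membership(cl)))
    best <- as.integer(igraph::membership(cl))
    if (k == n_clusters) break
    if (k < n_clusters) lo <- mid else hi <- mid
  }
  best
}

#' Supervised clustering metrics
#'
#' Computes the six standard agreement metrics between a predicted partition
#' and ground-truth labels from their contingency table: homogeneity, mutual
#' information (in nats), V-measure, adjusted mutual information (AMI,
#' arithmetic normalisation), normalised mutual information (NMI, arithmetic
#' normalisation) and the adjusted Rand index (ARI). All are invariant to
#' permutations of the cluster identifiers.
#'
#' @param pred predicted cluster labels.
#' @param truth ground-truth labels (>= 2 classes).
#' @return Named numeric vector with elements `homogeneity`, `mutual_info`,
#'   `v_measure`, `ami`, `nmi`, `ari`.
#' @export
cluster_metrics <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth must have the same length")
  truth <- as.factor(truth)
  pred <- as.factor(pred)
  if (nlevels(droplevels(truth)) < 2L)
    stop("truth must contain at least 2 classes")
  ct <- table(truth, pred)
  N <- sum(ct)
  a <- rowSums(ct); b <- colSums(ct)
  Ht <- .entropy(a, N)
  Hp <- .entropy(b, N)
  mi <- .mutual_information(ct, N)
  homogeneity <- if (Ht == 0) 1 else mi / Ht
  completeness <- if (Hp == 0) 1 else mi / Hp
  v_measure <- if (homogeneity + completeness == 0) 0 else
    2 * homogeneity * completeness / (homogeneity + completeness)
  denom <- (Ht + Hp) / 2
  nmi <- if (denom == 0) 1 else mi / denom
  emi <- .expected_mi(a, b, N)
  ami_den <- denom - emi
  ami <- if (abs(ami_den) < .Machine$double.eps) {
    if (abs(mi - emi) < .Machine$double.eps) 1 else 0
  } else (mi - emi) / ami_den
  c(homogeneity = homogeneity, mutual_info = mi, v_measure = v_measure,
    ami = ami, nmi = nmi, ari = .ari(ct, a, b, N))
}

#' Cluster-count sweep
#'
#' Clusters the embedding at every cluster count in `k_range` under every
#' seed, scoring each partition with [cluster_metrics()]; the summary medians
#' per k are the box-plot statistic of the evaluation protocol.
#'
#' @param h embedding matrix.
#' @param truth ground-truth labels.
#' @param k_range integer vector of cluster counts (default 4:11).
#' @param seeds integer vector of clustering seeds (default 0:4).
#' @param method passed to [cluster_embeddings()].
#' @return Long-form data frame with columns `n_clusters`, `seed` and the
#'   six metrics; per-k medians attached as `attr(, "summary")`.
#' @export
sweep_clusters <- function(h, truth, k_range = 4:11, seeds = 0:4,
                           method = "kmeans") {
  stopifnot(length(k_range) >= 1L)
  rows <- list()
  for (k in k_range) {
    for (s in seeds) {
      lab <- cluster_embeddings(h, k, seed = s, method = method)
      rows[[length(rows) + 1L]] <-
        data.frame(n_clusters = k, seed = s,
                   as.list(cluster_metrics(lab, truth)))
    }
  }
  out <- do.call(rbind, rows)
  metric_cols <- c("homogeneity", "mutual_info", "v_measure", "ami", "nmi", "ari")
  summ <- stats::aggregate(out[metric_cols],
                           list(n_clusters = out$n_clusters), stats::median)
  attr(out, "summary") <- summ
  out
}

# ---------------------------------------------------------------------------

.entropy <- function(counts, N) {
  p <- counts[counts > 0] / N
  -sum(p * log(p))
}

.mutual_information <- function(ct, N) {
  idx <- which(ct > 0, arr.ind = TRUE)
  nij <- ct[idx]
  ai <- rowSums(ct)[idx[, 1]]
  bj <- colSums(ct)[idx[, 2]]
  sum(nij / N * log(N * nij / (ai * bj)))
}

# expected mutual information under the hypergeometric model of random
# labelings with fixed marginals
.expected_mi <- function(a, b, N) {
  emi <- 0
  lgN <- lgamma(N + 1)
  for (ai in a) {
    for (bj in b) {
      lo <- max(1L, ai + bj - N)
      hi <- min(ai, bj)
      if (lo > hi) next
      nij <- lo:hi
      term <- nij / N * log(N * nij / (ai * bj))
      lp <- lgamma(ai + 1) + lgamma(bj + 1) +
        lgamma(N - ai + 1) + lgamma(N - bj + 1) -
        lgN - lgamma(nij + 1) - lgamma(ai - nij + 1) -
        lgamma(bj - nij + 1) - lgamma(N - ai - bj + nij + 1)
      emi <- emi + sum(term * exp(lp))
    }
  }
  emi
}

.ari <- function(ct, a, b, N) {
  comb2 <- function(x) x * (x - 1) / 2
  index <- sum(comb2(ct))
  sa <- sum(comb2(a)); sb <- sum(comb2(b))
  expected <- sa * sb / comb2(N)
  maxi <- (sa + sb) / 2
  if (maxi == expected) return(1)
  (index - expected) / (maxi - expected)
}
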