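#' K-nearest-neighbour graph from feature similarity
#'
#' Connects each spot to the `k` spots with the most similar molecular
#' profile. Similarity is Pearson correlation between spot rows by default,
#' with cosine similarity as an alternative. The resulting graph is directed
#' (row-wise top-k): row i has exactly `k` ones, the diagonal is zero. Ties
#' are broken deterministically in favour of the lowest spot index.
#'
#' @param x numeric matrix, spots x features.
#' @param k number of neighbours, `1 <= k < nrow(x)`.
#' @param similarity `"pearson"` (default) or `"cosine"`.
#' @param symmetrize if `TRUE`, OR the adjacency with its transpose (row sums
#'   then exceed `k` where links are not reciprocated); default `FALSE`.
#' @return A `neighbor_graph`: list with `adjacency` (sparse N x N 0/1
#'   `dgCMatrix`), `k`, `source = "feature"`, `similarity`, `symmetrized`.
#' @export
knn_feature_graph <- function(x, k, similarity = c("pearson", "cosine"),
                              symmetrize = FALSE) {
  similarity <- match.arg(similarity)
  x <- as.matrix(x)
  n <- nrow(x)
  .check_k(k, n)
  if (similarity == "pearson") {
    rv <- apply(x, 1L, stats::var)
    if (any(rv == 0)) {
      bad <- which(rv == 0)
      stop("zero-variance spot row(s) make Pearson similarity undefined: ",
           paste(utils::head(.row_ids(x, bad), 5L), collapse = ", "),
           if (length(bad) > 5L) " ..." else "")
    }
    s <- stats::cor(t(x))
  } else {
    nr <- sqrt(rowSums(x^2))
    if (any(nr == 0)) {
      bad <- which(nr == 0)
      stop("all-zero spot row(s) make cosine similarity undefined: ",
           paste(utils::head(.row_ids(x, bad), 5L), collapse = ", "),
           if (length(bad) > 5L) " ..." else "")
    }
    s <- tcrossprod(x / nr)
  }
  adj <- .topk_adjacency(s, k, decreasing = TRUE)
  if (symmetrize) adj <- .or_sym(adj)
  .new_neighbor_graph(adj, k, "feature", similarity = similarity,
                      symmetrized = symmetrize)
}

#' K-nearest-neighbour graph from spatial proximity
#'
#' Connects each spot to the `k` physically closest spots by Euclidean
#' distance between coordinates. Directed row-wise top-k, diagonal zero, ties
#' broken by lowest spot index. Duplicated coordinates (distance zero) are
#' allowed; a message reports them.
#'
#' @param coords numeric matrix, spots x 2, physical coordinates.
#' @param k number of neighbours, `1 <= k < nrow(coords)`.
#' @param symmetrize as in [knn_feature_graph()].
#' @return A `neighbor_graph` with `source = "spatial"`.
#' @export
knn_spatial_graph <- function(coords, k, symmetrize = FALSE) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  .check_k(k, n)
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  d <- as.matrix(stats::dist(coords))
  ndup <- sum(d[upper.tri(d)] == 0)
  if (ndup > 0)
    message("knn_spatial_graph: ", ndup, " spot pair(s) share identical coordinates")
  adj <- .topk_adjacency(-d, k, decreasing = TRUE)
  if (symmetrize) adj <- .or_sym(adj)
  .new_neighbor_graph(adj, k, "spatial", similarity = "euclidean",
                      symmetrized = symmetrize)
}

#' Build the four neighbour graphs of a paired dataset
#'
#' For a two-modality spatial dataset the model uses four graphs: one
#' feature-similarity graph per modality and one spatial-proximity graph per
#' modality. Both spatial graphs are built from the same coordinates, so they
#' are identical when `k_spat` is shared.
#'
#' @param pair a [spatial_omics_pair()].
#' @param k_feat neighbours for the feature graphs (default 20).
#' @param k_spat neighbours for the spatial graphs (default 20).
#' @param similarity passed to [knn_feature_graph()].
#' @param symmetrize passed to both builders.
#' @return A list `f1`, `f2`, `s1`, `s2` of `neighbor_graph` objects with the
#'   `modality` field set.
#' @export
neighbor_graphs <- function(pair, k_feat = 20L, k_spat = 20L,
                            similarity = c("pearson", "cosine"),
                            symmetrize = FALSE) {
  stopifnot(inherits(pair, "spatial_omics_pair"))
  similarity <- match.arg(similarity)
  f1 <- knn_feature_graph(pair$x1, k_feat, similarity, symmetrize)
  f2 <- knn_feature_graph(pair$x2, k_feat, similarity, symmetrize)
  s1 <- knn_spatial_graph(pair$coords, k_spat, symmetrize)
  s2 <- s1
  f1$modality <- 1L; s1$modality <- 1L
  f2$modality <- 2L; s2$modality <- 2L
  list(f1 = f1, f2 = f2, s1 = s1, s2 = s2)
}

#' @method print neighbor_graph
#' @export
print.neighbor_graph <- function(x, ...) {
  cat("neighbor_graph (", x$source, "): ", nrow(x$adjacency), " spots, k = ",
      x$k, ", ", length(x$adjacency@x), " edges",
      if (isTRUE(x$symmetrized)) ", symmetrized" else "", "\n", sep = "")
  invisible(x)
}

#' Export a neighbour graph as an edge list with a JSON sidecar
#'
#' Writes a two-column TSV of (i, j) 1-based edge indices plus
#' `<path>.json` recording k, source, similarity and symmetrization, so a
#' graph can be reconstructed or audited outside R.
#'
#' @param graph a `neighbor_graph`.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_graph_tsv <- function(graph, path) {
  stopifnot(inherits(graph, "neighbor_graph"))
  tm <- Matrix::summary(graph$adjacency)
  ord <- order(tm$i, tm$j)
  utils::write.table(data.frame(i = tm$i[ord], j = tm$j[ord]), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(k = graph$k, source = graph$source,
               similarity = graph$similarity,
               symmetrized = isTRUE(graph$symmetrized),
               n_spots = nrow(graph$adjacency))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

.check_k <- function(k, n) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("k must be a positive integer")
  if (k >= n)
    stop("k (", k, ") must be smaller than the number of spots (", n, ")")
}

.row_ids <- function(x, idx) {
  if (!is.null(rownames(x))) rownames(x)[idx] else as.character(idx)
}

# Row-wise top-k of a dense score matrix, self excluded, ties broken by
# lowest column index (order() is stable for equal keys).
.topk_adjacency <- function(score, k, decreasing = TRUE) {
  n <- nrow(score)
  diag(score) <- -Inf
  jj <- integer(n * k)
  for (i in seq_len(n)) {
    ord <- order(score[i, ], decreasing = decreasing)
    jj[((i - 1L) * k + 1L):(i * k)] <- ord[seq_len(k)]
  }
  ii <- rep(seq_len(n), each = k)
  Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
}

.or_sym <- function(adj) {
  s <- adj + Matrix::t(adj)
  s@x[] <- 1
  s
}

.new_neighbor_graph <- function(adj, k, source, similarity, symmetrized) {
  structure(list(adjacency = methods::as(adj, "CsparseMatrix"),
                 k = as.integer(k), source = source,
                 similarity = similarity, symmetrized = symmetrized,
                 modality = NA_integer_),
            class = "neighbor_graph")
}
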