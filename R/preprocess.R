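# Modality-appropriate preprocessing: gene filtering, library-size
# normalisation with dispersion-ranked highly variable genes for RNA counts,
# TF-IDF + truncated SVD (latent semantic indexing) for chromatin peak
# counts, and centred log-ratio for protein panels.

#' Preprocessing recipe
#'
#' Bundles the preprocessing defaults applied by [preprocess_pair()]:
#' genes expressed in fewer than `min_spots_per_gene` spots are removed, RNA
#' counts are library-size normalised and log1p-transformed with the top
#' `n_hvg` highly variable genes kept, chromatin peak counts are reduced to
#' `lsi_dim` LSI components, and protein panels get the chosen per-spot
#' transform.
#'
#' @param min_spots_per_gene minimum spots with nonzero counts (default 10).
#' @param n_hvg number of highly variable genes (default 3000).
#' @param lsi_dim LSI components for peak counts (default 200).
#' @param log_normalize log-normalise RNA counts (default `TRUE`).
#' @param protein_transform `"clr"` (default), `"log1p"` or `"none"`.
#' @return List of class `preprocess_recipe`.
#' @export
preprocess_recipe <- function(min_spots_per_gene = 10L, n_hvg = 3000L,
                              lsi_dim = 200L, log_normalize = TRUE,
                              protein_transform = c("clr", "log1p", "none")) {
  protein_transform <- match.arg(protein_transform)
  structure(list(min_spots_per_gene = as.integer(min_spots_per_gene),
                 n_hvg = as.integer(n_hvg), lsi_dim = as.integer(lsi_dim),
                 log_normalize = isTRUE(log_normalize),
                 protein_transform = protein_transform),
            class = "preprocess_recipe")
}

#' Filter rarely expressed genes
#'
#' Keeps exactly the features with nonzero counts in at least `min_spots`
#' spots.
#'
#' @param x count matrix, spots x genes.
#' @param min_spots minimum number of spots with a nonzero count.
#' @return List with `x` (reduced matrix) and `kept` (column indices kept).
#' @export
filter_genes <- function(x, min_spots = 10L) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("filter_genes expects non-negative counts")
  kept <- which(colSums(x > 0) >= min_spots)
  if (length(kept) == 0L)
    stop("all features filtered out at min_spots = ", min_spots)
  list(x = x[, kept, drop = FALSE], kept = kept)
}

#' Log-normalisation and highly variable gene selection
#'
#' Scales each spot's counts to the median total count, applies `log1p`, and
#' keeps the `n_hvg` most variable genes by the dispersion-based ranking:
#' per-gene dispersion (variance over mean of the normalised counts) is
#' z-scored within 20 equal-width mean-expression bins and the genes with the
#' highest normalised dispersion are kept, original column order preserved.
#'
#' @param x count matrix, spots x genes (already filtered).
#' @param n_hvg genes to keep; if `n_hvg >= ncol(x)` all genes are kept.
#' @return List with `x` (log-normalised matrix restricted to the selected
#'   genes), `hvg` (column indices selected, in original order) and
#'   `size_factors`.
#' @export
lognorm_hvg <- function(x, n_hvg = 3000L) {
  x <- as.matrix(x)
  if (n_hvg <= 0) stop("n_hvg must be positive")
  totals <- rowSums(x)
  if (any(totals == 0)) stop("spot(s) with zero total counts: ",
                             paste(utils::head(which(totals == 0), 5), collapse = ", "))
  sf <- totals / stats::median(totals)
  xn <- x / sf
  lg <- log1p(xn)
  if (n_hvg >= ncol(x)) {
    return(list(x = lg, hvg = seq_len(ncol(x)), size_factors = sf))
  }
  mu <- colMeans(xn)
  v <- apply(xn, 2L, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(mu, breaks = 20L, labels = FALSE, include.lowest = TRUE)
  zdisp <- disp
  gm <- mean(disp); gs <- stats::sd(disp)
  if (!is.finite(gs) || gs == 0) gs <- 1
  for (b in unique(bins)) {
    ix <- which(bins == b)
    if (length(ix) < 2L) {
      # a bin with a single gene has no within-bin spread; rank the gene
      # against the global dispersion distribution instead of zeroing it out
      zdisp[ix] <- (disp[ix] - gm) / gs
      next
    }
    m <- mean(disp[ix]); s <- stats::sd(disp[ix])
    if (!is.finite(s) || s == 0) s <- 1
    zdisp[ix] <- (disp[ix] - m) / s
  }
  sel <- sort(order(-zdisp)[seq_len(n_hvg)])
  list(x = lg[, sel, drop = FALSE], hvg = sel, size_factors = sf)
}

#' Latent semantic indexing of peak counts
#'
#' TF-IDF weighting (term frequency per spot times inverse document
#' frequency `log(1 + N / df)`), log-scaling, and truncated SVD to `dim`
#' components. The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making the reduction
#' deterministic. The first component, which typically tracks sequencing
#' depth, can be dropped.
#'
#' @param x non-negative peak count matrix, spots x peaks.
#' @param dim number of components (must satisfy `dim < min(N, P)`).
#' @param drop_first drop the first (depth-correlated) component; the output
#'   then still has `dim` columns (components 2..dim+1).
#' @return Matrix, spots x `dim`.
#' @export
lsi_reduce <- function(x, dim = 200L, drop_first = FALSE) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("lsi_reduce expects non-negative counts")
  n <- nrow(x); p <- ncol(x)
  ncomp <- dim + as.integer(drop_first)
  if (ncomp >= min(n, p))
    stop("dim (", dim, ") must be smaller than min(n_spots, n_peaks) = ",
         min(n, p))
  totals <- rowSums(x)
  if (any(totals == 0)) stop("spot(s) with zero total counts")
  df <- colSums(x > 0)
  if (any(df == 0)) {
    message("lsi_reduce: dropping ", sum(df == 0), " all-zero peak(s)")
    x <- x[, df > 0, drop = FALSE]
    df <- df[df > 0]
  }
  tf <- x / totals
  idf <- log(1 + n / df)
  m <- log1p(sweep(tf, 2L, idf, "*") * 1e4)
  sv <- svd(m, nu = ncomp, nv = ncomp)
  u <- sv$u; v <- sv$v
  for (c in seq_len(ncomp)) {
    s <- sign(v[which.max(abs(v[, c])), c])
    if (s < 0) { u[, c] <- -u[, c]; v[, c] <- -v[, c] }
  }
  scores <- u %*% diag(sv$d[seq_len(ncomp)], ncomp)
  if (drop_first) scores <- scores[, -1L, drop = FALSE]
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("LSI", seq_len(ncol(scores)))
  scores
}

#' Centred log-ratio transform
#'
#' Per-spot `log1p(x) - mean(log1p(x))`, the conventional normalisation for
#' antibody-panel counts.
#'
#' @param x non-negative count matrix, spots x proteins.
#' @return Transformed matrix of the same shape.
#' @export
clr_transform <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("clr_transform expects non-negative counts")
  lg <- log1p(x)
  lg - rowMeans(lg)
}

#' Preprocess a raw paired dataset
#'
#' Applies the recipe to both modalities: modality 1 is treated as RNA counts
#' (filter, log-normalise, HVG); modality 2 is treated according to
#' `modality2` as a protein panel (per-spot transform), chromatin peak counts
#' (LSI), or passed through unchanged.
#'
#' @param pair a raw-count [spatial_omics_pair()].
#' @param recipe a [preprocess_recipe()].
#' @param modality2 `"protein"` (default), `"peaks"` or `"none"`.
#' @return A new `spatial_omics_pair` of processed matrices, with the recipe
#'   and the kept-feature indices attached as attributes `recipe` and
#'   `kept_features`.
#' @export
preprocess_pair <- function(pair, recipe = preprocess_recipe(),
                            modality2 = c("protein", "peaks", "none")) {
  stopifnot(inherits(pair, "spatial_omics_pair"),
            inherits(recipe, "preprocess_recipe"))
  modality2 <- match.arg(modality2)
  fg <- filter_genes(pair$x1, recipe$min_spots_per_gene)
  x1 <- fg$x
  hvg <- NULL
  if (recipe$log_normalize) {
    ln <- lognorm_hvg(x1, recipe$n_hvg)
    x1 <- ln$x
    hvg <- fg$kept[ln$hvg]
  }
  x2 <- switch(modality2,
    protein = switch(recipe$protein_transform,
      clr = clr_transform(pair$x2),
      log1p = log1p(pair$x2),
      none = pair$x2),
    peaks = lsi_reduce(pair$x2, recipe$lsi_dim),
    none = pair$x2)
  out <- spatial_omics_pair(x1, x2, pair$coords, pair$spot_ids, pair$labels)
  attr(out, "recipe") <- recipe
  attr(out, "kept_features") <- list(modality1 = hvg %||% fg$kept)
  out
}
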