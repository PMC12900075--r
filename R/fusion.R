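# Attention-based fusion of view/modality embeddings: a two-layer
# feed-forward attention network scores each input embedding per spot and the
# fused embedding is the per-spot convex combination.

#' Initialise fusion attention parameters
#'
#' @param d embedding width of the inputs.
#' @param d_att width of the attention hidden layer (defaults to `d`).
#' @return List of class `fusion_params` with `W` (`d` x `d_att`) and `u`
#'   (length `d_att`), Glorot-initialised from the current RNG.
#' @export
init_fusion_params <- function(d, d_att = d) {
  stopifnot(d >= 1L, d_att >= 1L)
  structure(list(W = .glorot(d, d_att),
                 u = drop(.glorot(d_att, 1L))),
            class = "fusion_params")
}

#' Attention fusion of embeddings
#'
#' Given `m` embeddings of the same spots, computes per-spot scores
#' `v = tanh(Z W)`, attention weights `alpha = softmax(v' u)` over the `m`
#' inputs, and the fused embedding `Z' = sum_i alpha_i Z_i`. With
#' `per_spot = TRUE` (default) every spot gets its own weight vector; with
#' `per_spot = FALSE` a single global weight vector (scores averaged over
#' spots) is used, provided for ablation.
#'
#' @param z_list list of `m >= 2` numeric matrices, all N x D.
#' @param params a [init_fusion_params()] list.
#' @param per_spot per-spot weights (default) or one global weight vector.
#' @return List of class `fusion_result` with `z_fused` (N x D) and `alpha`
#'   (N x m; every row is non-negative and sums to 1).
#' @export
attention_fuse <- function(z_list, params, per_spot = TRUE) {
  stopifnot(is.list(z_list), length(z_list) >= 2L)
  z_list <- lapply(z_list, as.matrix)
  dims <- vapply(z_list, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all fusion inputs must share the same dimensions; got ",
         paste(apply(dims, 2, paste, collapse = "x"), collapse = ", "))
  fr <- .fuse_fwd(z_list, params, per_spot)
  structure(list(z_fused = fr$z, alpha = fr$alpha), class = "fusion_result")
}

#' Two-level fusion hierarchy
#'
#' Fuses the four view embeddings exactly as the model does: the feature and
#' spatial views of modality 1 are fused into `h_mod1`, those of modality 2
#' into `h_mod2`, and the two modality embeddings into `h_combine`. The three
#' fusion blocks have independent parameters.
#'
#' @param z_f1,z_s1,z_f2,z_s2 the four view embeddings (N x D each).
#' @param params3 list of three [init_fusion_params()] (intra-modality 1,
#'   intra-modality 2, cross-modal).
#' @param labels optional factor of cluster/domain labels; when given, a
#'   per-cluster summary of the attention weights is attached.
#' @param per_spot see [attention_fuse()].
#' @return List with `h_mod1`, `h_mod2`, `h_combine` (each a
#'   `fusion_result`) and `weight_report` (per-cluster mean weights, or
#'   `NULL` without labels).
#' @export
fuse_hierarchy <- function(z_f1, z_s1, z_f2, z_s2, params3, labels = NULL,
                           per_spot = TRUE) {
  stopifnot(length(params3) == 3L)
  h1 <- attention_fuse(list(z_f1, z_s1), params3[[1]], per_spot)
  h2 <- attention_fuse(list(z_f2, z_s2), params3[[2]], per_spot)
  hc <- attention_fuse(list(h1$z_fused, h2$z_fused), params3[[3]], per_spot)
  colnames(h1$alpha) <- colnames(h2$alpha) <- c("feature", "spatial")
  colnames(hc$alpha) <- c("modality1", "modality2")
  wr <- NULL
  if (!is.null(labels)) {
    wr <- list(intra_mod1 = .cluster_mean(h1$alpha, labels),
               intra_mod2 = .cluster_mean(h2$alpha, labels),
               cross = .cluster_mean(hc$alpha, labels))
  }
  list(h_mod1 = h1, h_mod2 = h2, h_combine = hc, weight_report = wr)
}

#' Per-cluster summary of learned attention weights
#'
#' Averages the per-spot fusion weights of a fitted model within each cluster
#' or annotated domain: the interpretability output showing which view
#' (feature vs spatial) and which modality the model relied on per region.
#' Each summary row is itself a distribution summing to 1.
#'
#' @param fit a [gatfuse()] fit.
#' @param labels factor of cluster assignments or annotations, one per spot;
#'   defaults to the fitted pair's ground-truth labels if present.
#' @return List of three matrices (clusters x inputs): `intra_mod1`,
#'   `intra_mod2`, `cross`.
#' @export
attention_weight_report <- function(fit, labels = NULL) {
  stopifnot(inherits(fit, "gatfuse"))
  if (is.null(labels)) labels <- fit$labels
  if (is.null(labels))
    stop("no labels available; pass cluster assignments explicitly")
  labels <- as.factor(labels)
  aw <- fit$attention_weights
  list(intra_mod1 = .cluster_mean(aw$intra_mod1, labels),
       intra_mod2 = .cluster_mean(aw$intra_mod2, labels),
       cross = .cluster_mean(aw$cross, labels))
}

#' Write per-spot and per-cluster fusion weights as TSV
#'
#' @param fit a [gatfuse()] fit.
#' @param dir output directory.
#' @param labels optional labels for the per-cluster summary.
#' @return Invisibly, `dir`.
#' @export
write_attention_weights <- function(fit, dir, labels = NULL) {
  stopifnot(inherits(fit, "gatfuse"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (lv in names(fit$attention_weights)) {
    m <- fit$attention_weights[[lv]]
    df <- data.frame(spot = fit$spot_ids, m, check.names = FALSE)
    utils::write.table(df, file.path(dir, paste0("alpha_", lv, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (is.null(labels)) labels <- fit$labels
  if (!is.null(labels)) {
    rep <- attention_weight_report(fit, labels)
    for (lv in names(rep)) {
      df <- data.frame(cluster = rownames(rep[[lv]]), rep[[lv]],
                       check.names = FALSE)
      utils::write.table(df, file.path(dir, paste0("alpha_", lv, "_by_cluster.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  invisible(dir)
}

.cluster_mean <- function(alpha, labels) {
  out <- rowsum(alpha, labels) / as.vector(table(labels))
  out
}

# forward with cache for training
.fuse_fwd <- function(z_list, params, per_spot = TRUE) {
  m <- length(z_list)
  n <- nrow(z_list[[1]])
  V <- lapply(z_list, function(z) tanh(z %*% params$W))
  e <- vapply(V, function(v) drop(v %*% params$u), numeric(n))
  if (!is.matrix(e)) e <- matrix(e, nrow = n)
  if (!per_spot) e <- matrix(colMeans(e), n, m, byrow = TRUE)
  emax <- do.call(pmax, lapply(seq_len(m), function(i) e[, i]))
  ee <- exp(e - emax)
  alpha <- ee / rowSums(ee)
  z <- matrix(0, n, ncol(z_list[[1]]))
  for (i in seq_len(m)) z <- z + alpha[, i] * z_list[[i]]
  list(z = z, alpha = alpha,
       cache = list(z_list = z_list, V = V, per_spot = per_spot))
}

.fuse_bwd <- function(dz, fwd, params) {
  cache <- fwd$cache
  z_list <- cache$z_list
  alpha <- fwd$alpha
  m <- length(z_list)
  n <- nrow(dz)
  dalpha <- vapply(z_list, function(z) rowSums(dz * z), numeric(n))
  if (!is.matrix(dalpha)) dalpha <- matrix(dalpha, nrow = n)
  dz_list <- lapply(seq_len(m), function(i) alpha[, i] * dz)
  srow <- rowSums(alpha * dalpha)
  de <- alpha * (dalpha - srow)
  if (!cache$per_spot) de <- matrix(colMeans(de), n, m, byrow = TRUE) # chain rule of the score averaging
  gW <- matrix(0, nrow(params$W), ncol(params$W))
  gu <- 0 * params$u
  for (i in seq_len(m)) {
    gu <- gu + drop(crossprod(cache$V[[i]], de[, i]))
    dV <- outer(de[, i], params$u) * (1 - cache$V[[i]]^2)
    gW <- gW + crossprod(z_list[[i]], dV)
    dz_list[[i]] <- dz_list[[i]] + tcrossprod(dV, params$W)
  }
  list(dz_list = dz_list, W = gW, u = gu)
}
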