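# Joint training: four GAT encoders -> two-level attention fusion -> two GAT
# decoders, optimised with Adam on the weighted sum of the two reconstruction
# losses and the cross-modal contrastive loss.

#' Mean squared reconstruction loss
#'
#' `(1/N) * sum_i || z_dec_i - x_i ||^2`: squared Euclidean residual per
#' spot, averaged over spots.
#'
#' @param z_dec reconstruction matrix (N x F).
#' @param x target matrix (N x F).
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(z_dec, x) {
  z_dec <- as.matrix(z_dec); x <- as.matrix(x)
  if (!all(dim(z_dec) == dim(x)))
    stop("reconstruction and target dimensions differ: ",
         paste(dim(z_dec), collapse = "x"), " vs ",
         paste(dim(x), collapse = "x"))
  sum((z_dec - x)^2) / nrow(x)
}

#' Weighted total loss
#'
#' `lambda1 * L_recon1 + lambda2 * L_recon2 + lambda3 * L_cl`.
#'
#' @param l_r1,l_r2 reconstruction losses of the two modalities.
#' @param l_cl contrastive loss.
#' @param lambda numeric vector of three non-negative weights.
#' @return Scalar.
#' @export
total_loss <- function(l_r1, l_r2, l_cl, lambda = c(1, 1, 0.1)) {
  stopifnot(length(lambda) == 3L, all(lambda >= 0), sum(lambda) > 0)
  stopifnot(is.finite(l_r1), is.finite(l_r2), is.finite(l_cl))
  lambda[1] * l_r1 + lambda[2] * l_r2 + lambda[3] * l_cl
}

#' Fit the joint spatial multi-omics model
#'
#' Builds the four neighbour graphs, encodes each (matrix, graph) view with
#' its own multi-layer GAT encoder, fuses the views per modality and then
#' across modalities with attention fusion, decodes the combined embedding
#' back into both feature spaces with symmetric GAT decoders, and trains the
#' whole model full-batch with Adam on
#' `lambda1 * L_recon1 + lambda2 * L_recon2 + lambda3 * L_cl`.
#' The contrastive loss is computed on the two post-intra-fusion modality
#' embeddings; its temperature is annealed multiplicatively on a fixed step
#' schedule (or, with `learnable_tau = TRUE`, updated by gradient instead).
#'
#' All randomness (initialisation, dropout, negative sampling) derives from
#' `seed`; two fits with identical inputs and seed produce identical
#' embeddings.
#'
#' @param pair a [spatial_omics_pair()] (already preprocessed; see
#'   [preprocess_pair()]).
#' @param k_feat,k_spat neighbours for the feature/spatial graphs.
#' @param similarity feature-graph similarity (see [knn_feature_graph()]).
#' @param symmetrize symmetrize the KNN graphs (default `FALSE`).
#' @param hidden hidden layer width(s) of each encoder (default 128; chosen
#'   so a full fit of a few hundred spots completes in under a minute on one
#'   CPU core; wider encoders give indistinguishable clustering quality on
#'   the bundled benchmarks).
#' @param latent latent embedding width (default 64).
#' @param heads attention heads per GAT layer.
#' @param dropout dropout rate during training.
#' @param epochs full-batch training steps (default 150).
#' @param lr Adam learning rate.
#' @param weight_decay Adam weight decay.
#' @param lambda length-3 weights of (recon modality 1, recon modality 2,
#'   contrastive) losses.
#' @param contrastive a [contrastive_config()].
#' @param learnable_tau update the temperature by gradient instead of the
#'   annealing schedule (mutually exclusive modes).
#' @param attention `"learned"` (default) or `"uniform"` (mean-over-
#'   neighbours aggregation; the attention-free ablation).
#' @param decoder_graph which graph the decoders aggregate over:
#'   `"spatial"` (default) or `"feature"`.
#' @param per_spot_fusion per-spot fusion weights (default) or global.
#' @param grad_clip global gradient-norm clip (default 5).
#' @param seed integer seed controlling all randomness.
#' @param verbose print the loss every 50 epochs.
#' @return An object of class `gatfuse`; see the package vignette. Key
#'   fields: `embedding` (N x latent combined embedding), `views`,
#'   `modality_embeddings`, `attention_weights`, `reconstructions`, `log`
#'   (per-epoch losses and temperature), `losses` (final evaluation-mode
#'   losses), `config`, `graphs`, `diverged`.
#' @seealso [predict.gatfuse()], [run_ablation()], [cluster_embeddings()]
#' @export
gatfuse <- function(pair,
                    k_feat = 20L, k_spat = 20L,
                    similarity = c("pearson", "cosine"),
                    symmetrize = FALSE,
                    hidden = 128L, latent = 64L, heads = 1L,
                    dropout = 0.1,
                    epochs = 150L, lr = 1e-3, weight_decay = 0,
                    lambda = c(1, 1, 0.1),
                    contrastive = contrastive_config(),
                    learnable_tau = FALSE,
                    attention = c("learned", "uniform"),
                    decoder_graph = c("spatial", "feature"),
                    per_spot_fusion = TRUE,
                    grad_clip = 5,
                    seed = 0L, verbose = FALSE) {
  stopifnot(inherits(pair, "spatial_omics_pair"))
  similarity <- match.arg(similarity)
  attention <- match.arg(attention)
  decoder_graph <- match.arg(decoder_graph)
  stopifnot(length(lambda) == 3L, all(lambda >= 0), sum(lambda) > 0)

  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(seed)

  x1 <- pair$x1; x2 <- pair$x2
  n <- pair$n_spots
  graphs <- neighbor_graphs(pair, k_feat = k_feat, k_spat = k_spat,
                            similarity = similarity, symmetrize = symmetrize)
  pg <- lapply(graphs, .prep_graph, self_loops = TRUE)
  pg_dec1 <- if (decoder_graph == "spatial") pg$s1 else pg$f1
  pg_dec2 <- if (decoder_graph == "spatial") pg$s2 else pg$f2

  widths1 <- c(ncol(x1), hidden, latent)
  widths2 <- c(ncol(x2), hidden, latent)
  model <- list(
    enc = list(
      f1 = init_gat_stack(widths1, heads, dropout, "encoder"),
      s1 = init_gat_stack(widths1, heads, dropout, "encoder"),
      f2 = init_gat_stack(widths2, heads, dropout, "encoder"),
      s2 = init_gat_stack(widths2, heads, dropout, "encoder")),
    dec = list(
      d1 = init_gat_stack(rev(widths1), heads, dropout, "decoder"),
      d2 = init_gat_stack(rev(widths2), heads, dropout, "decoder")),
    fus = list(m1 = init_fusion_params(latent),
               m2 = init_fusion_params(latent),
               x = init_fusion_params(latent)))

  state <- list(tau = contrastive$tau, step = 0L,
                anneal_factor = contrastive$anneal_factor,
                anneal_every = contrastive$anneal_every,
                tau_floor = contrastive$tau_floor)
  opt <- .adam_init(lr = lr, weight_decay = weight_decay)
  log <- vector("list", epochs)
  prev <- model
  prev_tau <- state$tau
  diverged <- FALSE

  for (epoch in seq_len(epochs)) {
    cfg <- contrastive
    cfg$tau <- state$tau
    fw <- .model_fwd(model, x1, x2, pg, pg_dec1, pg_dec2, cfg,
                     mode = attention, per_spot = per_spot_fusion,
                     training = TRUE, need_cl = lambda[3] > 0,
                     grad = TRUE)
    ltot <- lambda[1] * fw$l_r1 + lambda[2] * fw$l_r2 + lambda[3] * fw$l_cl
    if (!is.finite(ltot)) {
      warning("training diverged at epoch ", epoch,
              "; returning the last finite state")
      model <- prev
      state$tau <- prev_tau
      diverged <- TRUE
      log <- log[seq_len(epoch - 1L)]
      break
    }
    prev <- model
    prev_tau <- state$tau
    log[[epoch]] <- data.frame(step = epoch, loss_recon1 = fw$l_r1,
                               loss_recon2 = fw$l_r2, loss_cl = fw$l_cl,
                               tau = state$tau, total = ltot)
    if (verbose && (epoch == 1L || epoch %% 50L == 0L))
      message(sprintf("epoch %4d  total %.4f  (r1 %.4f r2 %.4f cl %.4f tau %.4f)",
                      epoch, ltot, fw$l_r1, fw$l_r2, fw$l_cl, state$tau))

    gr <- .model_bwd(model, fw, x1, x2, pg, pg_dec1, pg_dec2, lambda,
                     mode = attention)
    flatP <- .model_leaves(model)
    flatG <- gr
    if (learnable_tau && lambda[3] > 0) {
      flatP$tau <- state$tau
      flatG$tau <- lambda[3] * fw$dtau
    }
    flatG <- .clip_grads(flatG, grad_clip)
    upd <- .adam_step(opt, flatP, flatG)
    opt <- upd$opt
    if (learnable_tau && lambda[3] > 0) {
      state$tau <- max(upd$params$tau, contrastive$tau_floor)
      upd$params$tau <- NULL
    }
    model <- .set_model_leaves(model, upd$params)
    state$step <- state$step + 1L
    if (!learnable_tau) state <- anneal_temperature(state)
  }

  log <- do.call(rbind, log)
  cfg <- contrastive
  cfg$tau <- state$tau
  ev <- .model_fwd(model, x1, x2, pg, pg_dec1, pg_dec2, cfg,
                   mode = attention, per_spot = per_spot_fusion,
                   training = FALSE, need_cl = TRUE, grad = FALSE)

  config <- list(k_feat = k_feat, k_spat = k_spat, similarity = similarity,
                 symmetrize = symmetrize, hidden = hidden, latent = latent,
                 heads = heads, dropout = dropout, epochs = epochs, lr = lr,
                 weight_decay = weight_decay, lambda = lambda,
                 contrastive = unclass(contrastive),
                 learnable_tau = learnable_tau, attention = attention,
                 decoder_graph = decoder_graph,
                 per_spot_fusion = per_spot_fusion, grad_clip = grad_clip,
                 seed = seed)
  aw <- list(intra_mod1 = ev$fu1$alpha, intra_mod2 = ev$fu2$alpha,
             cross = ev$fuc$alpha)
  colnames(aw$intra_mod1) <- colnames(aw$intra_mod2) <- c("feature", "spatial")
  colnames(aw$cross) <- c("modality1", "modality2")
  rownames(aw$intra_mod1) <- rownames(aw$intra_mod2) <-
    rownames(aw$cross) <- pair$spot_ids

  manifest <- list(
    layer_shapes = lapply(c(model$enc, model$dec), function(s) s$widths),
    config_hash = .hash_config(config),
    seed = seed, n_spots = n,
    package_version = as.character(utils::packageVersion("gatfuse")))

  fit <- list(
    embedding = `rownames<-`(ev$fuc$z, pair$spot_ids),
    views = list(f1 = ev$zf1, s1 = ev$zs1, f2 = ev$zf2, s2 = ev$zs2),
    modality_embeddings = list(mod1 = ev$fu1$z, mod2 = ev$fu2$z),
    attention_weights = aw,
    reconstructions = list(mod1 = ev$zd1, mod2 = ev$zd2),
    losses = c(recon1 = ev$l_r1, recon2 = ev$l_r2, cl = ev$l_cl,
               total = lambda[1] * ev$l_r1 + lambda[2] * ev$l_r2 +
                 lambda[3] * ev$l_cl),
    log = log, model = model, tau = state$tau, graphs = graphs,
    coords = pair$coords, labels = pair$labels, spot_ids = pair$spot_ids,
    x1 = x1, x2 = x2,
    config = config, manifest = manifest, diverged = diverged,
    call = match.call())
  class(fit) <- "gatfuse"
  fit
}

#' Run the component ablations
#'
#' Fits the full model, the model without contrastive learning (`no_cl`:
#' contrastive weight set to zero) and the model without attention
#' (`no_gat`: every neighbour weighted uniformly) over a set of seeds, then
#' clusters each combined embedding and scores it against the pair's
#' ground-truth labels with the six supervised metrics.
#'
#' @param pair a labelled [spatial_omics_pair()].
#' @param variants subset of `c("full", "no_cl", "no_gat")`.
#' @param seeds integer vector of fit seeds.
#' @param n_clusters clusters for scoring; defaults to the number of true
#'   domains.
#' @param ... further arguments to [gatfuse()].
#' @return A data frame with one row per (variant, seed): the six metrics and
#'   the final training losses (`loss_cl` is `NA` for `no_cl`). A per-variant
#'   median summary is attached as `attr(, "summary")`.
#' @export
run_ablation <- function(pair, variants = c("full", "no_cl", "no_gat"),
                         seeds = 0:4, n_clusters = NULL, ...) {
  stopifnot(inherits(pair, "spatial_omics_pair"))
  if (is.null(pair$labels))
    stop("run_ablation needs ground-truth labels for metric computation")
  bad <- setdiff(variants, c("full", "no_cl", "no_gat"))
  if (length(bad)) stop("unknown variant(s): ", paste(bad, collapse = ", "))
  if (is.null(n_clusters)) n_clusters <- nlevels(pair$labels)
  dots <- list(...)
  rows <- list()
  for (v in variants) {
    for (s in seeds) {
      args <- c(list(pair = pair, seed = s), dots)
      if (v == "no_cl") {
        lam <- args$lambda %||% c(1, 1, 0.1)
        lam[3] <- 0
        args$lambda <- lam
      }
      if (v == "no_gat") args$attention <- "uniform"
      fit <- do.call(gatfuse, args)
      lab <- cluster_embeddings(fit$embedding, n_clusters, seed = s)
      met <- cluster_metrics(lab, pair$labels)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, seed = s, n_clusters = n_clusters,
        as.list(met),
        loss_recon1 = unname(fit$losses["recon1"]),
        loss_recon2 = unname(fit$losses["recon2"]),
        loss_cl = if (v == "no_cl") NA_real_ else unname(fit$losses["cl"]))
    }
  }
  out <- do.call(rbind, rows)
  metric_cols <- c("homogeneity", "mutual_info", "v_measure", "ami", "nmi", "ari")
  summ <- stats::aggregate(out[metric_cols], list(variant = out$variant),
                           stats::median)
  attr(out, "summary") <- summ
  out
}

#' Save / load a fitted model
#'
#' The checkpoint is a single serialized file; the fit's `manifest` (layer
#' shapes, configuration hash, seed, package version) travels inside it and
#' is validated on load.
#'
#' @param fit a [gatfuse()] fit.
#' @param path file path.
#' @return `save_gatfuse` invisibly returns `path`; `load_gatfuse` returns
#'   the fit.
#' @export
save_gatfuse <- function(fit, path) {
  stopifnot(inherits(fit, "gatfuse"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_gatfuse
#' @export
load_gatfuse <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "gatfuse") || is.null(fit$manifest))
    stop("not a gatfuse checkpoint: ", path)
  if (!identical(fit$manifest$config_hash, .hash_config(fit$config)))
    stop("checkpoint manifest does not match its configuration")
  fit
}

# ---------------------------------------------------------------------------
# forward / backward over the whole model

.model_fwd <- function(model, x1, x2, pg, pg_dec1, pg_dec2, cl_cfg,
                       mode, per_spot, training, need_cl, grad) {
  ef1 <- .gat_stack_fwd(x1, pg$f1, model$enc$f1, mode, training)
  es1 <- .gat_stack_fwd(x1, pg$s1, model$enc$s1, mode, training)
  ef2 <- .gat_stack_fwd(x2, pg$f2, model$enc$f2, mode, training)
  es2 <- .gat_stack_fwd(x2, pg$s2, model$enc$s2, mode, training)
  fu1 <- .fuse_fwd(list(ef1$out, es1$out), model$fus$m1, per_spot)
  fu2 <- .fuse_fwd(list(ef2$out, es2$out), model$fus$m2, per_spot)
  fuc <- .fuse_fwd(list(fu1$z, fu2$z), model$fus$x, per_spot)
  d1 <- .gat_stack_fwd(fuc$z, pg_dec1, model$dec$d1, mode, training)
  d2 <- .gat_stack_fwd(fuc$z, pg_dec2, model$dec$d2, mode, training)
  l_r1 <- reconstruction_loss(d1$out, x1)
  l_r2 <- reconstruction_loss(d2$out, x2)
  cl <- NULL; l_cl <- 0; dtau <- 0
  if (need_cl) {
    cl <- contrastive_loss(fu1$z, fu2$z, cl_cfg, grad = grad)
    if (grad) {
      l_cl <- cl$loss
      dtau <- cl$dtau %||% 0
    } else l_cl <- cl
  }
  list(ef1 = ef1, es1 = es1, ef2 = ef2, es2 = es2,
       fu1 = fu1, fu2 = fu2, fuc = fuc, d1 = d1, d2 = d2,
       zf1 = ef1$out, zs1 = es1$out, zf2 = ef2$out, zs2 = es2$out,
       zd1 = d1$out, zd2 = d2$out,
       l_r1 = l_r1, l_r2 = l_r2, l_cl = l_cl, cl = cl, dtau = dtau)
}

.model_bwd <- function(model, fw, x1, x2, pg, pg_dec1, pg_dec2, lambda,
                       mode) {
  n <- nrow(x1)
  g1 <- lambda[1] * 2 * (fw$d1$out - x1) / n
  g2 <- lambda[2] * 2 * (fw$d2$out - x2) / n
  bd1 <- .gat_stack_bwd(g1, fw$d1$caches, model$dec$d1, pg_dec1, mode)
  bd2 <- .gat_stack_bwd(g2, fw$d2$caches, model$dec$d2, pg_dec2, mode)
  dHc <- bd1$dx + bd2$dx
  bfc <- .fuse_bwd(dHc, fw$fuc, model$fus$x)
  dH1 <- bfc$dz_list[[1]]
  dH2 <- bfc$dz_list[[2]]
  if (lambda[3] > 0 && !is.null(fw$cl)) {
    dH1 <- dH1 + lambda[3] * fw$cl$dh1
    dH2 <- dH2 + lambda[3] * fw$cl$dh2
  }
  bf1 <- .fuse_bwd(dH1, fw$fu1, model$fus$m1)
  bf2 <- .fuse_bwd(dH2, fw$fu2, model$fus$m2)
  be_f1 <- .gat_stack_bwd(bf1$dz_list[[1]], fw$ef1$caches, model$enc$f1, pg$f1, mode)
  be_s1 <- .gat_stack_bwd(bf1$dz_list[[2]], fw$es1$caches, model$enc$s1, pg$s1, mode)
  be_f2 <- .gat_stack_bwd(bf2$dz_list[[1]], fw$ef2$caches, model$enc$f2, pg$f2, mode)
  be_s2 <- .gat_stack_bwd(bf2$dz_list[[2]], fw$es2$caches, model$enc$s2, pg$s2, mode)
  c(.stack_grad_leaves(be_f1$layers, "enc.f1"),
    .stack_grad_leaves(be_s1$layers, "enc.s1"),
    .stack_grad_leaves(be_f2$layers, "enc.f2"),
    .stack_grad_leaves(be_s2$layers, "enc.s2"),
    .stack_grad_leaves(bd1$layers, "dec.d1"),
    .stack_grad_leaves(bd2$layers, "dec.d2"),
    stats::setNames(list(bf1$W, bf1$u, bf2$W, bf2$u, bfc$W, bfc$u),
                    c("fus.m1.W", "fus.m1.u", "fus.m2.W", "fus.m2.u",
                      "fus.x.W", "fus.x.u")))
}

# ---------------------------------------------------------------------------
# parameter flattening and Adam

.stack_leaf_names <- function(stack, prefix) {
  out <- character(0)
  for (l in seq_along(stack$layers)) {
    par <- stack$layers[[l]]
    base <- paste0(prefix, ".L", l, ".")
    for (k in seq_len(par$heads))
      out <- c(out, paste0(base, c("W", "a_src", "a_dst"), k))
    out <- c(out, paste0(base, c("gamma", "beta")))
    if (!is.null(par$W_res)) out <- c(out, paste0(base, "W_res"))
  }
  out
}

.stack_leaves <- function(stack, prefix) {
  out <- list()
  for (l in seq_along(stack$layers)) {
    par <- stack$layers[[l]]
    base <- paste0(prefix, ".L", l, ".")
    for (k in seq_len(par$heads)) {
      out[[paste0(base, "W", k)]] <- par$W[[k]]
      out[[paste0(base, "a_src", k)]] <- par$a_src[[k]]
      out[[paste0(base, "a_dst", k)]] <- par$a_dst[[k]]
    }
    out[[paste0(base, "gamma")]] <- par$gamma
    out[[paste0(base, "beta")]] <- par$beta
    if (!is.null(par$W_res)) out[[paste0(base, "W_res")]] <- par$W_res
  }
  out
}

.stack_grad_leaves <- function(layer_grads, prefix) {
  out <- list()
  for (l in seq_along(layer_grads)) {
    gr <- layer_grads[[l]]
    base <- paste0(prefix, ".L", l, ".")
    for (k in seq_along(gr$W)) {
      out[[paste0(base, "W", k)]] <- gr$W[[k]]
      out[[paste0(base, "a_src", k)]] <- gr$a_src[[k]]
      out[[paste0(base, "a_dst", k)]] <- gr$a_dst[[k]]
    }
    out[[paste0(base, "gamma")]] <- gr$gamma
    out[[paste0(base, "beta")]] <- gr$beta
    if (!is.null(gr$W_res)) out[[paste0(base, "W_res")]] <- gr$W_res
  }
  out
}

.model_leaves <- function(model) {
  c(.stack_leaves(model$enc$f1, "enc.f1"),
    .stack_leaves(model$enc$s1, "enc.s1"),
    .stack_leaves(model$enc$f2, "enc.f2"),
    .stack_leaves(model$enc$s2, "enc.s2"),
    .stack_leaves(model$dec$d1, "dec.d1"),
    .stack_leaves(model$dec$d2, "dec.d2"),
    stats::setNames(list(model$fus$m1$W, model$fus$m1$u,
                         model$fus$m2$W, model$fus$m2$u,
                         model$fus$x$W, model$fus$x$u),
                    c("fus.m1.W", "fus.m1.u", "fus.m2.W", "fus.m2.u",
                      "fus.x.W", "fus.x.u")))
}

.set_stack_leaves <- function(stack, flat, prefix) {
  for (l in seq_along(stack$layers)) {
    par <- stack$layers[[l]]
    base <- paste0(prefix, ".L", l, ".")
    for (k in seq_len(par$heads)) {
      par$W[[k]] <- flat[[paste0(base, "W", k)]]
      par$a_src[[k]] <- flat[[paste0(base, "a_src", k)]]
      par$a_dst[[k]] <- flat[[paste0(base, "a_dst", k)]]
    }
    par$gamma <- flat[[paste0(base, "gamma")]]
    par$beta <- flat[[paste0(base, "beta")]]
    if (!is.null(par$W_res)) par$W_res <- flat[[paste0(base, "W_res")]]
    stack$layers[[l]] <- par
  }
  stack
}

.set_model_leaves <- function(model, flat) {
  model$enc$f1 <- .set_stack_leaves(model$enc$f1, flat, "enc.f1")
  model$enc$s1 <- .set_stack_leaves(model$enc$s1, flat, "enc.s1")
  model$enc$f2 <- .set_stack_leaves(model$enc$f2, flat, "enc.f2")
  model$enc$s2 <- .set_stack_leaves(model$enc$s2, flat, "enc.s2")
  model$dec$d1 <- .set_stack_leaves(model$dec$d1, flat, "dec.d1")
  model$dec$d2 <- .set_stack_leaves(model$dec$d2, flat, "dec.d2")
  model$fus$m1$W <- flat[["fus.m1.W"]]; model$fus$m1$u <- flat[["fus.m1.u"]]
  model$fus$m2$W <- flat[["fus.m2.W"]]; model$fus$m2$u <- flat[["fus.m2.u"]]
  model$fus$x$W <- flat[["fus.x.W"]]; model$fus$x$u <- flat[["fus.x.u"]]
  model
}

.clip_grads <- function(flatG, clip) {
  if (is.null(clip) || !is.finite(clip) || clip <= 0) return(flatG)
  total <- sqrt(sum(vapply(flatG, function(g) sum(g^2), numeric(1))))
  if (total > clip) flatG <- lapply(flatG, function(g) g * clip / total)
  flatG
}

.adam_init <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 0) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       weight_decay = weight_decay, t = 0L, m = list(), v = list())
}

.adam_step <- function(opt, flatP, flatG) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(flatP)) {
    g <- flatG[[nm]]
    if (is.null(g)) next
    if (opt$weight_decay > 0) g <- g + opt$weight_decay * flatP[[nm]]
    if (is.null(opt$m[[nm]])) {
      opt$m[[nm]] <- 0 * g
      opt$v[[nm]] <- 0 * g
    }
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    flatP[[nm]] <- flatP[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  list(opt = opt, params = flatP)
}

# ---------------------------------------------------------------------------
# small utilities

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

.hash_config <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
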