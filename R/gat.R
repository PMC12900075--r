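# Graph attention layers: forward passes for the public API plus analytic
# backward passes used by the training loop. The implementation is edge-list
# based (softmax over each node's neighbour set), with a sparse
# attention-matrix product doing the aggregation.

LEAKY_SLOPE <- 0.2
LN_EPS <- 1e-5

#' Initialise one graph attention layer
#'
#' Creates the trainable parameters of a single GAT layer: per-head linear
#' maps `W` (`f_in` x `f_head`), per-head attention vectors split into source
#' and destination halves (`a = [a_src; a_dst]`, each of length `f_head`),
#' layer-norm affine parameters, and a residual projection when the input and
#' output widths differ. Multi-head outputs are concatenated, so the output
#' width is `heads * f_head`. Initialisation is uniform Glorot, drawn from the
#' current RNG state.
#'
#' @param f_in input feature width.
#' @param f_head per-head output width.
#' @param heads number of attention heads (>= 1; concatenated).
#' @param act activation applied in the layer update: `"elu"` or
#'   `"identity"`.
#' @param use_ln apply layer normalisation in the layer update.
#' @return A list of class `gat_layer_params`.
#' @export
init_gat_layer <- function(f_in, f_head, heads = 1L, act = "elu",
                           use_ln = TRUE) {
  stopifnot(heads >= 1L, f_in >= 1L, f_head >= 1L)
  f_out <- heads * f_head
  W <- lapply(seq_len(heads), function(k) .glorot(f_in, f_head))
  a_src <- lapply(seq_len(heads), function(k) drop(.glorot(2L * f_head, 1L))[seq_len(f_head)])
  a_dst <- lapply(seq_len(heads), function(k) drop(.glorot(2L * f_head, 1L))[seq_len(f_head)])
  par <- list(W = W, a_src = a_src, a_dst = a_dst,
              gamma = rep(1, f_out), beta = rep(0, f_out),
              W_res = if (f_in != f_out) .glorot(f_in, f_out) else NULL,
              heads = as.integer(heads), f_in = as.integer(f_in),
              f_head = as.integer(f_head), f_out = as.integer(f_out),
              act = act, use_ln = isTRUE(use_ln))
  class(par) <- "gat_layer_params"
  par
}

#' Initialise a multi-layer graph attention stack
#'
#' Builds an encoder or decoder as a sequence of GAT layers with the given
#' widths. All layers but the last use the chosen activation and layer
#' normalisation; the final layer is linear without normalisation, so an
#' encoder ends in an unconstrained latent space and a decoder ends in the
#' original feature space.
#'
#' @param widths integer vector of layer widths including the input width,
#'   e.g. `c(50, 256, 64)` for a two-layer encoder.
#' @param heads attention heads per layer (recycled).
#' @param dropout dropout rate applied after layer norm during training.
#' @param role `"encoder"` or `"decoder"` (bookkeeping; decoders are
#'   validated to mirror their encoder's widths by [gatfuse()]).
#' @param act activation for the non-final layers.
#' @return A list of class `gat_stack`.
#' @export
init_gat_stack <- function(widths, heads = 1L, dropout = 0.1,
                           role = c("encoder", "decoder"), act = "elu") {
  role <- match.arg(role)
  stopifnot(length(widths) >= 2L, dropout >= 0, dropout < 1)
  L <- length(widths) - 1L
  heads <- rep_len(as.integer(heads), L)
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    last <- l == L
    if (widths[l + 1L] %% heads[l] != 0L)
      stop("layer ", l, ": width ", widths[l + 1L],
           " not divisible by ", heads[l], " heads")
    layers[[l]] <- init_gat_layer(widths[l], widths[l + 1L] %/% heads[l],
                                  heads = heads[l],
                                  act = if (last) "identity" else act,
                                  use_ln = !last)
  }
  structure(list(layers = layers, dropout = dropout, role = role,
                 widths = as.integer(widths)),
            class = "gat_stack")
}

#' Attention coefficients of one GAT layer
#'
#' For every directed edge (i, j) of the graph and every head, computes the
#' softmax-normalised attention weight
#' `alpha_ij = softmax_j(LeakyReLU(a' [W x_i || W x_j]))`, the softmax taken
#' over j in the neighbour set of i. By default a self-loop is added to every
#' node so no softmax has empty support.
#'
#' @param x node feature matrix (N x f_in).
#' @param graph a `neighbor_graph` or a binary adjacency matrix.
#' @param params a [init_gat_layer()] parameter list.
#' @param self_loops add self-edges before attention (default `TRUE`).
#' @param mode `"learned"` (default) or `"uniform"` (each neighbour weighted
#'   `1/|N(i)|`; the attention-free ablation).
#' @return A list with `i`, `j` (1-based edge endpoints, sorted by `i`) and
#'   `alpha`, an edges x heads matrix; each node's edge weights sum to 1 per
#'   head.
#' @export
gat_attention <- function(x, graph, params, self_loops = TRUE,
                          mode = c("learned", "uniform")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  pg <- .prep_graph(graph, self_loops = self_loops)
  K <- params$heads
  alpha <- matrix(0, length(pg$iE), K)
  for (k in seq_len(K)) {
    if (mode == "uniform") {
      alpha[, k] <- 1 / pg$deg[pg$iE]
    } else {
      P <- x %*% params$W[[k]]
      s <- drop(P %*% params$a_src[[k]])
      tt <- drop(P %*% params$a_dst[[k]])
      pre <- .leaky(s[pg$iE] + tt[pg$jE])
      alpha[, k] <- .group_softmax(pre, pg)
    }
  }
  list(i = pg$iE, j = pg$jE, alpha = alpha, n = pg$n)
}

#' Forward pass of one GAT layer (aggregation only)
#'
#' Computes `H_i = ||_k sum_{j in N(i)} alpha_ij^(k) W^(k) x_j`, i.e. the
#' attention-weighted neighbour aggregation, with multi-head results
#' concatenated. This is the raw layer output before activation,
#' normalisation and the residual update (see [gat_layer_update()]).
#'
#' @inheritParams gat_attention
#' @return Matrix N x (heads * f_head).
#' @export
gat_layer <- function(x, graph, params, self_loops = TRUE,
                      mode = c("learned", "uniform")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (ncol(x) != params$f_in)
    stop("width mismatch in GAT layer: input has ", ncol(x),
         " features, layer expects ", params$f_in)
  pg <- .prep_graph(graph, self_loops = self_loops)
  .gat_layer_fwd(x, pg, params, mode)$H
}

#' Residual layer update
#'
#' Applies `X_out = Dropout(LayerNorm(act(H))) + Proj(X_prev)`, where `Proj`
#' is the layer's residual projection when widths differ and the identity
#' otherwise. In evaluation mode (`training = FALSE`, the default) dropout is
#' the identity.
#'
#' @param h raw layer output from [gat_layer()].
#' @param x_prev the layer's input (residual branch).
#' @param params the layer's parameters.
#' @param dropout dropout rate (used only when `training = TRUE`).
#' @param training enable dropout sampling from the current RNG.
#' @return Matrix with the width of `h`.
#' @export
gat_layer_update <- function(h, x_prev, params, dropout = 0,
                             training = FALSE) {
  .layer_update_fwd(as.matrix(h), as.matrix(x_prev), params,
                    dropout = dropout, training = training)$out
}

#' Encode node features through a GAT stack
#'
#' Runs `L` layer-forward + layer-update steps and returns the final
#' embedding. With `training = FALSE` (default) the pass is deterministic.
#'
#' @param x node feature matrix.
#' @param graph a `neighbor_graph` or adjacency matrix.
#' @param stack a [init_gat_stack()] with role `"encoder"`.
#' @inheritParams gat_attention
#' @param training enable dropout.
#' @return Embedding matrix N x final width.
#' @export
gat_encode <- function(x, graph, stack, self_loops = TRUE,
                       mode = c("learned", "uniform"), training = FALSE) {
  mode <- match.arg(mode)
  pg <- .prep_graph(graph, self_loops = self_loops)
  .gat_stack_fwd(as.matrix(x), pg, stack, mode = mode,
                 training = training)$out
}

#' Decode an embedding back to feature space through a GAT stack
#'
#' Identical computation to [gat_encode()] but run with a decoder stack whose
#' final width is the target modality's feature count.
#'
#' @param h embedding matrix (N x latent width).
#' @inheritParams gat_encode
#' @param stack a [init_gat_stack()] with role `"decoder"`.
#' @return Reconstruction matrix N x feature count.
#' @export
gat_decode <- function(h, graph, stack, self_loops = TRUE,
                       mode = c("learned", "uniform"), training = FALSE) {
  mode <- match.arg(mode)
  pg <- .prep_graph(graph, self_loops = self_loops)
  .gat_stack_fwd(as.matrix(h), pg, stack, mode = mode,
                 training = training)$out
}

# ---------------------------------------------------------------------------
# internal machinery

.glorot <- function(f_in, f_out) {
  lim <- sqrt(6 / (f_in + f_out))
  matrix(stats::runif(f_in * f_out, -lim, lim), f_in, f_out)
}

.leaky <- function(z) {
  neg <- which(z < 0)   # which() drops NaN so poisoned inputs pass through
  z[neg] <- LEAKY_SLOPE * z[neg]
  z
}

.elu <- function(z) {
  neg <- which(z < 0)
  z[neg] <- exp(z[neg]) - 1
  z
}

.elu_grad <- function(z) {
  g <- array(1, dim(z))
  neg <- which(z < 0)
  g[neg] <- exp(z[neg])
  g
}

# Prepare an adjacency for edge-wise attention: sorted edge list, degrees,
# and a CSC template so per-edge weights can be loaded into a sparse matrix
# without re-sorting triplets on every call.
.prep_graph <- function(graph, self_loops = TRUE) {
  if (inherits(graph, "gatfuse_prep_graph")) return(graph)
  adj <- if (inherits(graph, "neighbor_graph")) graph$adjacency else graph
  adj <- methods::as(methods::as(as(adj, "CsparseMatrix"), "generalMatrix"), "dMatrix")
  n <- nrow(adj)
  if (self_loops) adj <- adj + Matrix::Diagonal(n)
  deg_all <- Matrix::rowSums(adj != 0)
  if (any(deg_all == 0))
    stop("isolated node(s) with empty neighbourhood and no self-loop: ",
         paste(utils::head(which(deg_all == 0), 10L), collapse = ", "))
  tm <- Matrix::summary(methods::as(adj, "CsparseMatrix"))
  ord <- order(tm$i, tm$j)
  iE <- tm$i[ord]; jE <- tm$j[ord]
  deg <- tabulate(iE, n)
  d <- if (length(unique(deg)) == 1L) deg[1L] else NA_integer_
  tpl <- Matrix::sparseMatrix(i = iE, j = jE, x = seq_along(iE),
                              dims = c(n, n))
  csc_perm <- as.integer(tpl@x)
  grp <- if (is.na(d))
    split(seq_along(iE), factor(iE, levels = seq_len(n)))
  else NULL
  structure(list(n = n, iE = iE, jE = jE, deg = deg, d = d,
                 tpl = tpl, csc_perm = csc_perm, grp = grp),
            class = "gatfuse_prep_graph")
}

# numerically stable softmax over the edge groups of each source node
.group_softmax <- function(z, pg) {
  if (!is.na(pg$d)) {
    zm <- matrix(z, nrow = pg$d)
    mi <- max.col(t(zm), ties.method = "first")
    m <- zm[cbind(mi, seq_len(pg$n))]
    ez <- exp(z - m[pg$iE])
    s <- colSums(matrix(ez, nrow = pg$d))
    ez / s[pg$iE]
  } else {
    m <- vapply(pg$grp, function(ix) max(z[ix]), numeric(1))
    ez <- exp(z - m[pg$iE])
    s <- vapply(pg$grp, function(ix) sum(ez[ix]), numeric(1))
    ez / s[pg$iE]
  }
}

.group_sum_i <- function(v, pg) {
  if (!is.na(pg$d)) colSums(matrix(v, nrow = pg$d))
  else vapply(pg$grp, function(ix) sum(v[ix]), numeric(1))
}

.group_sum_j <- function(v, pg) {
  out <- numeric(pg$n)
  agg <- rowsum(v, pg$jE)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

.alpha_spmat <- function(alpha, pg) {
  A <- pg$tpl
  A@x <- alpha[pg$csc_perm]
  A
}

.gat_layer_fwd <- function(x, pg, par, mode) {
  K <- par$heads
  P <- vector("list", K); alpha <- vector("list", K)
  pre <- vector("list", K); A <- vector("list", K)
  H <- matrix(0, pg$n, par$f_out)
  for (k in seq_len(K)) {
    P[[k]] <- x %*% par$W[[k]]
    if (mode == "uniform") {
      alpha[[k]] <- 1 / pg$deg[pg$iE]
      pre[[k]] <- NULL
    } else {
      s <- drop(P[[k]] %*% par$a_src[[k]])
      tt <- drop(P[[k]] %*% par$a_dst[[k]])
      raw <- s[pg$iE] + tt[pg$jE]
      pre[[k]] <- raw
      alpha[[k]] <- .group_softmax(.leaky(raw), pg)
    }
    A[[k]] <- .alpha_spmat(alpha[[k]], pg)
    cols <- ((k - 1L) * par$f_head + 1L):(k * par$f_head)
    H[, cols] <- as.matrix(A[[k]] %*% P[[k]])
  }
  if (any(!is.finite(H)))
    stop("non-finite values in GAT layer output")
  list(H = H, cache = list(x = x, P = P, alpha = alpha, pre = pre, A = A))
}

.gat_layer_bwd <- function(dH, cache, par, pg, mode) {
  K <- par$heads
  dx <- matrix(0, nrow(cache$x), par$f_in)
  gW <- vector("list", K); ga_src <- vector("list", K); ga_dst <- vector("list", K)
  for (k in seq_len(K)) {
    cols <- ((k - 1L) * par$f_head + 1L):(k * par$f_head)
    dM <- dH[, cols, drop = FALSE]
    P <- cache$P[[k]]
    dP <- as.matrix(Matrix::crossprod(cache$A[[k]], dM))
    if (mode == "learned") {
      # per-edge d(loss)/d(alpha): entries of dM P' at the edge positions
      dalpha <- if (nrow(dM) <= 4096L)
        tcrossprod(dM, P)[cbind(pg$iE, pg$jE)]
      else
        rowSums(dM[pg$iE, , drop = FALSE] * P[pg$jE, , drop = FALSE])
      S <- .group_sum_i(cache$alpha[[k]] * dalpha, pg)
      dE <- cache$alpha[[k]] * (dalpha - S[pg$iE])
      dpre <- dE * ifelse(cache$pre[[k]] > 0, 1, LEAKY_SLOPE)
      ds <- .group_sum_i(dpre, pg)
      dt <- .group_sum_j(dpre, pg)
      dP <- dP + outer(ds, par$a_src[[k]]) + outer(dt, par$a_dst[[k]])
      ga_src[[k]] <- drop(crossprod(P, ds))
      ga_dst[[k]] <- drop(crossprod(P, dt))
    } else {
      ga_src[[k]] <- 0 * par$a_src[[k]]
      ga_dst[[k]] <- 0 * par$a_dst[[k]]
    }
    gW[[k]] <- crossprod(cache$x, dP)
    dx <- dx + tcrossprod(dP, par$W[[k]])
  }
  list(dx = dx, W = gW, a_src = ga_src, a_dst = ga_dst)
}

.layer_update_fwd <- function(H, x_prev, par, dropout, training) {
  U <- if (par$act == "elu") .elu(H) else H
  if (par$use_ln) {
    mu <- rowMeans(U)
    Uc <- U - mu
    v <- rowMeans(Uc^2)
    inv <- 1 / sqrt(v + LN_EPS)
    xhat <- Uc * inv
    V <- sweep(sweep(xhat, 2L, par$gamma, "*"), 2L, par$beta, "+")
  } else {
    xhat <- NULL; inv <- NULL
    V <- U
  }
  if (training && dropout > 0) {
    mask <- matrix((stats::runif(length(V)) >= dropout) / (1 - dropout),
                   nrow(V), ncol(V))
    D <- V * mask
  } else {
    mask <- NULL
    D <- V
  }
  res <- if (is.null(par$W_res)) x_prev else x_prev %*% par$W_res
  out <- D + res
  list(out = out,
       cache = list(H = H, xhat = xhat, inv = inv, mask = mask,
                    x_prev = x_prev, dropout = dropout, training = training))
}

.layer_update_bwd <- function(dout, cache, par) {
  dx_prev <- if (is.null(par$W_res)) dout else tcrossprod(dout, par$W_res)
  gW_res <- if (is.null(par$W_res)) NULL else crossprod(cache$x_prev, dout)
  dV <- if (!is.null(cache$mask)) dout * cache$mask else dout
  if (par$use_ln) {
    ggamma <- colSums(dV * cache$xhat)
    gbeta <- colSums(dV)
    g <- sweep(dV, 2L, par$gamma, "*")
    dU <- cache$inv * (g - rowMeans(g) - cache$xhat * rowMeans(g * cache$xhat))
  } else {
    ggamma <- 0 * par$gamma
    gbeta <- 0 * par$beta
    dU <- dV
  }
  dH <- if (par$act == "elu") dU * .elu_grad(cache$H) else dU
  list(dH = dH, dx_prev = dx_prev, gamma = ggamma, beta = gbeta,
       W_res = gW_res)
}

.gat_stack_fwd <- function(x, pg, stack, mode, training) {
  caches <- vector("list", length(stack$layers))
  cur <- x
  for (l in seq_along(stack$layers)) {
    par <- stack$layers[[l]]
    lf <- .gat_layer_fwd(cur, pg, par, mode)
    uf <- .layer_update_fwd(lf$H, cur, par, dropout = stack$dropout,
                            training = training)
    if (any(!is.finite(uf$out)))
      stop("numerical failure (non-finite values) in ", stack$role,
           " layer ", l)
    caches[[l]] <- list(layer = lf$cache, update = uf$cache)
    cur <- uf$out
  }
  list(out = cur, caches = caches)
}

.gat_stack_bwd <- function(dout, caches, stack, pg, mode) {
  L <- length(stack$layers)
  grads <- vector("list", L)
  g <- dout
  for (l in rev(seq_len(L))) {
    par <- stack$layers[[l]]
    ub <- .layer_update_bwd(g, caches[[l]]$update, par)
    lb <- .gat_layer_bwd(ub$dH, caches[[l]]$layer, par, pg, mode)
    grads[[l]] <- list(W = lb$W, a_src = lb$a_src, a_dst = lb$a_dst,
                       gamma = ub$gamma, beta = ub$beta, W_res = ub$W_res)
    g <- lb$dx + ub$dx_prev
  }
  list(dx = g, layers = grads)
}
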