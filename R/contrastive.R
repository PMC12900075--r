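# Cross-modal contrastive alignment: spot-wise positives across the two
# modality embeddings, negatives over other spots, temperature-scaled
# softmax loss with multiplicative temperature annealing.

#' Contrastive-learning configuration
#'
#' @param tau initial temperature (> 0).
#' @param anneal_factor multiplicative annealing factor in (0, 1]; the
#'   temperature is multiplied by it on schedule.
#' @param anneal_every anneal every this many steps (default 100).
#' @param neg_strategy `"all"`: every other spot is a negative (default);
#'   `"sampled"`: `n_neg` spots drawn uniformly without replacement per spot
#'   from the current RNG.
#' @param n_neg number of sampled negatives (required for `"sampled"`).
#' @param tau_floor lower clamp for the temperature (default 1e-3).
#' @param standard_infonce if `TRUE`, negatives use only the cross-modal
#'   similarity of modality 1 against modality 2 (the textbook InfoNCE
#'   denominator) instead of the four-term negative similarity; provided for
#'   ablation, default `FALSE`.
#' @return List of class `contrastive_config`.
#' @export
contrastive_config <- function(tau = 0.5, anneal_factor = 0.9,
                               anneal_every = 100L,
                               neg_strategy = c("all", "sampled"),
                               n_neg = NULL, tau_floor = 1e-3,
                               standard_infonce = FALSE) {
  neg_strategy <- match.arg(neg_strategy)
  stopifnot(tau > 0, anneal_factor > 0, anneal_factor <= 1,
            anneal_every >= 1, tau_floor > 0)
  if (neg_strategy == "sampled" && (is.null(n_neg) || n_neg < 1))
    stop("neg_strategy = 'sampled' requires n_neg >= 1")
  structure(list(tau = tau, anneal_factor = anneal_factor,
                 anneal_every = as.integer(anneal_every),
                 neg_strategy = neg_strategy,
                 n_neg = if (is.null(n_neg)) NULL else as.integer(n_neg),
                 tau_floor = tau_floor,
                 standard_infonce = isTRUE(standard_infonce)),
            class = "contrastive_config")
}

#' Row-wise L2 normalisation
#'
#' Scales every row of a matrix to unit Euclidean norm.
#'
#' @param h numeric matrix (N x D).
#' @return Matrix of the same shape with unit-norm rows.
#' @export
l2_normalize <- function(h) {
  h <- as.matrix(h)
  nr <- sqrt(rowSums(h^2))
  if (any(nr == 0)) {
    bad <- which(nr == 0)
    stop("degenerate all-zero embedding row(s): ",
         paste(utils::head(.row_ids(h, bad), 5L), collapse = ", "))
  }
  h / nr
}

#' Positive-pair similarities
#'
#' Dot product between the two modalities' normalised embeddings of the same
#' spot.
#'
#' @param h1n,h2n row-normalised embedding matrices (see [l2_normalize()]).
#' @return Numeric vector of length N with entries in `[-1, 1]`.
#' @export
positive_similarity <- function(h1n, h2n) {
  stopifnot(all(dim(h1n) == dim(h2n)))
  rowSums(as.matrix(h1n) * as.matrix(h2n))
}

#' Negative-pair similarity of one spot pair
#'
#' The summed similarity between spots `i` and `j` across all four
#' modality combinations:
#' `<h1_i, h2_j> + <h2_i, h1_j> + <h2_i, h2_j> + <h1_i, h1_j>`.
#'
#' @param h1n,h2n row-normalised embedding matrices.
#' @param i,j distinct spot indices.
#' @return A single numeric value in `[-4, 4]`.
#' @export
negative_similarity <- function(h1n, h2n, i, j) {
  if (i == j) stop("invalid negative pair: i and j must differ (got i = j = ",
                   i, ")")
  h1n <- as.matrix(h1n); h2n <- as.matrix(h2n)
  sum(h1n[i, ] * h2n[j, ]) + sum(h2n[i, ] * h1n[j, ]) +
    sum(h2n[i, ] * h2n[j, ]) + sum(h1n[i, ] * h1n[j, ])
}

#' Cross-modal contrastive loss
#'
#' For each spot, a temperature-scaled softmax contrasts the positive
#' similarity (same spot across modalities) against the negative-pair
#' similarities to the spot's negative set, and the loss is the mean negative
#' log probability of the positive. Inputs are L2-normalised internally;
#' computation is log-sum-exp stabilised. The loss is finite but not
#' guaranteed non-negative (negative similarities range over `[-4, 4]`).
#' With a single spot there are no negatives and the loss is exactly 0.
#'
#' @param h1,h2 raw (unnormalised) embedding matrices, N x D.
#' @param config a [contrastive_config()].
#' @param grad if `TRUE`, also return the analytic gradients with respect to
#'   `h1` and `h2`.
#' @return The scalar loss, or (with `grad = TRUE`) a list
#'   `loss`, `dh1`, `dh2`.
#' @export
contrastive_loss <- function(h1, h2, config = contrastive_config(),
                             grad = FALSE) {
  h1 <- as.matrix(h1); h2 <- as.matrix(h2)
  if (!all(dim(h1) == dim(h2)))
    stop("h1 and h2 must have identical dimensions")
  n <- nrow(h1)
  if (n == 1L) {
    if (!grad) return(0)
    return(list(loss = 0, dh1 = 0 * h1, dh2 = 0 * h2))
  }
  A <- l2_normalize(h1)
  B <- l2_normalize(h2)
  tau <- config$tau
  Cab <- tcrossprod(A, B)
  if (config$standard_infonce) {
    Sneg <- Cab
  } else {
    Sneg <- Cab + t(Cab) + tcrossprod(A) + tcrossprod(B)
  }
  spos <- diag(Cab)
  # logits: column of the positive plus the negative set, per spot (row)
  Z <- Sneg / tau
  diag(Z) <- spos / tau
  mask <- .neg_mask(n, config)
  Z[!mask] <- -Inf
  diag(Z) <- spos / tau   # positive always included
  m <- apply(Z, 1L, max)
  EZ <- exp(Z - m)
  denom <- rowSums(EZ)
  loss <- -mean(spos / tau - (m + log(denom)))
  if (!is.finite(loss))
    stop("non-finite contrastive loss (first offending spot: ",
         which(!is.finite(spos / tau - (m + log(denom))))[1L], ")")
  if (!grad) return(loss)
  P <- EZ / denom
  G <- P / (n * tau)           # d loss / d logit, positives on the diagonal
  diag(G) <- (diag(P) - 1) / (n * tau)
  Gpos <- diag(diag(G))
  Goff <- G - Gpos
  if (config$standard_infonce) {
    dA <- Goff %*% B
    dB <- crossprod(Goff, A)
  } else {
    GS <- Goff + t(Goff)
    dA <- GS %*% B + GS %*% A
    dB <- GS %*% A + GS %*% B
  }
  dA <- dA + diag(Gpos) * B
  dB <- dB + diag(Gpos) * A
  Sfull <- Sneg
  diag(Sfull) <- spos
  dtau <- -sum(G * Sfull) / tau
  list(loss = loss,
       dh1 = .l2_norm_bwd(h1, A, dA),
       dh2 = .l2_norm_bwd(h2, B, dB),
       dtau = dtau)
}

#' Anneal the contrastive temperature
#'
#' Lowers the temperature whenever the step counter is a positive multiple
#' of `anneal_every`, clamped below at the temperature floor. After `s`
#' steps from `tau0` the temperature is exactly
#' `max(tau0 * factor^floor(s / anneal_every), tau_floor)`; the schedule is
#' evaluated in this closed form (the starting value is captured on the
#' first call) rather than by repeated multiplication, so it carries no
#' accumulated rounding drift.
#'
#' @param state a list with at least `tau` and `step`, plus `anneal_factor`,
#'   `anneal_every`, `tau_floor` (a training state or a
#'   [contrastive_config()] augmented with a `step`).
#' @return `state` with `tau` updated (and `tau0` recorded).
#' @export
anneal_temperature <- function(state) {
  stopifnot(!is.null(state$tau), !is.null(state$step))
  every <- state$anneal_every %||% 100L
  fac <- state$anneal_factor %||% 0.9
  floor_ <- state$tau_floor %||% 1e-3
  if (is.null(state$tau0)) state$tau0 <- state$tau
  if (state$step > 0 && state$step %% every == 0)
    state$tau <- max(state$tau0 * fac^(state$step %/% every), floor_)
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.neg_mask <- function(n, config) {
  if (config$neg_strategy == "all") {
    mask <- matrix(TRUE, n, n)
  } else {
    mask <- matrix(FALSE, n, n)
    nn <- min(config$n_neg, n - 1L)
    for (i in seq_len(n)) {
      cand <- setdiff(seq_len(n), i)
      mask[i, sample(cand, nn)] <- TRUE
    }
  }
  diag(mask) <- FALSE
  mask
}

# gradient of y = h / ||h|| rows: dh = (dy - y * <y, dy>) / ||h||
.l2_norm_bwd <- function(h, y, dy) {
  nr <- sqrt(rowSums(h^2))
  (dy - y * rowSums(y * dy)) / nr
}
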