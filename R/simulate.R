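# Synthetic paired spatial multi-omics data with planted domains. The
# generator emulates the structure the model assumes: spatially contiguous
# domains, domain-specific mean signal per modality with a tunable fraction
# of the signal shared across modalities, and per-feature noise.

#' Simulate a paired spatial multi-omics dataset with planted domains
#'
#' Spots are laid out on a 2-D lattice (`"grid"`, the default: domains are
#' contiguous rectangular tiles of an integer lattice), around Gaussian
#' domain centres (`"gaussian_blobs"`), or in vertical stripes over uniform
#' coordinates (`"stripes"`). Each domain has its own mean profile in both
#' modalities, built from latent domain codes: modality 2's codes mix a
#' component shared with modality 1 (weight `sqrt(redundancy)`) with an
#' independent component (weight `sqrt(1 - redundancy)`), so `redundancy`
#' controls how much domain signal the modalities share. Features are the
#' domain mean scaled by `signal_strength` plus unit-variance Gaussian noise,
#' so `signal_strength` is the domain-mean separation in noise-SD units;
#' with `noise = "nb"` negative-binomial counts with a log-link on the same
#' signal are drawn instead.
#'
#' @param n_spots number of spots (>= 10 * n_domains).
#' @param n_domains number of planted domains (>= 2).
#' @param layout `"grid"`, `"gaussian_blobs"` or `"stripes"`.
#' @param f1,f2 feature counts of the two modalities.
#' @param signal_strength domain-mean separation in noise-SD units
#'   (0 = pure noise).
#' @param redundancy fraction of domain signal shared between modalities,
#'   in `[0, 1]`.
#' @param noise `"gaussian"` (default) or `"nb"` (negative-binomial counts).
#' @param nb_size negative-binomial size (inverse dispersion) for
#'   `noise = "nb"`.
#' @param latent_dim width of the latent domain codes (default 8).
#' @param seed integer seed; the output is fully reproducible.
#' @return A labelled [spatial_omics_pair()]; the simulation settings are
#'   attached as `attr(, "sim_config")`.
#' @export
simulate_spatial_pair <- function(n_spots = 600L, n_domains = 4L,
                                  layout = c("grid", "gaussian_blobs", "stripes"),
                                  f1 = 50L, f2 = 30L,
                                  signal_strength = 3, redundancy = 0.5,
                                  noise = c("gaussian", "nb"), nb_size = 10,
                                  latent_dim = 8L, seed = 0L) {
  layout <- match.arg(layout)
  noise <- match.arg(noise)
  if (n_domains < 2L) stop("n_domains must be at least 2")
  if (n_spots < 10L * n_domains)
    stop("n_spots must be at least 10 * n_domains")
  if (redundancy < 0 || redundancy > 1) stop("redundancy must be in [0, 1]")
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)

  lay <- switch(layout,
                grid = .layout_grid(n_spots, n_domains),
                gaussian_blobs = .layout_blobs(n_spots, n_domains),
                stripes = .layout_stripes(n_spots, n_domains))
  labels <- lay$labels

  q <- latent_dim
  C1 <- matrix(stats::rnorm(n_domains * q), n_domains, q)
  C_ind <- matrix(stats::rnorm(n_domains * q), n_domains, q)
  C2 <- sqrt(redundancy) * C1 + sqrt(1 - redundancy) * C_ind
  A1 <- matrix(stats::rnorm(q * f1), q, f1) / sqrt(q)
  A2 <- matrix(stats::rnorm(q * f2), q, f2) / sqrt(q)
  M1 <- C1 %*% A1   # n_domains x f1 domain profiles, unit-scale entries
  M2 <- C2 %*% A2

  S1 <- signal_strength * M1[labels, , drop = FALSE]
  S2 <- signal_strength * M2[labels, , drop = FALSE]
  if (noise == "gaussian") {
    x1 <- S1 + matrix(stats::rnorm(n_spots * f1), n_spots, f1)
    x2 <- S2 + matrix(stats::rnorm(n_spots * f2), n_spots, f2)
  } else {
    mu1 <- exp(log(5) + 0.25 * S1)
    mu2 <- exp(log(5) + 0.25 * S2)
    x1 <- matrix(stats::rnbinom(n_spots * f1, mu = mu1, size = nb_size),
                 n_spots, f1)
    x2 <- matrix(stats::rnbinom(n_spots * f2, mu = mu2, size = nb_size),
                 n_spots, f2)
  }
  colnames(x1) <- paste0("g", seq_len(f1))
  colnames(x2) <- paste0("p", seq_len(f2))
  pair <- spatial_omics_pair(x1, x2, lay$coords,
                             labels = factor(paste0("domain_", labels)))
  attr(pair, "sim_config") <- list(
    n_spots = n_spots, n_domains = n_domains, layout = layout,
    f1 = f1, f2 = f2, signal_strength = signal_strength,
    redundancy = redundancy, noise = noise, nb_size = nb_size,
    latent_dim = latent_dim, seed = seed)
  pair
}

#' Negative control: shuffle the domains away from the geography
#'
#' Simulates a dataset as [simulate_spatial_pair()] and then applies one
#' random permutation jointly to the feature matrices and labels while
#' leaving the coordinates fixed. Feature structure (which spots share a
#' domain profile) is preserved; spatial structure (domains forming
#' contiguous regions) is destroyed. Useful for testing that spatial graphs
#' carry information only when geography is informative.
#'
#' @inheritParams simulate_spatial_pair
#' @param ... passed to [simulate_spatial_pair()].
#' @return A labelled [spatial_omics_pair()].
#' @export
simulate_negative_control <- function(..., seed = 0L) {
  pair <- simulate_spatial_pair(..., seed = seed)
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed + 1000003L)
  perm <- sample.int(pair$n_spots)
  out <- spatial_omics_pair(pair$x1[perm, , drop = FALSE],
                            pair$x2[perm, , drop = FALSE],
                            pair$coords,
                            spot_ids = pair$spot_ids,
                            labels = pair$labels[perm])
  attr(out, "sim_config") <- attr(pair, "sim_config")
  out
}

# contiguous rectangular tiles of an nr x nc integer lattice
.layout_grid <- function(n, k) {
  nr <- floor(sqrt(n))
  while (nr > 1 && n %% nr != 0) nr <- nr - 1
  nc <- n / nr
  coords <- cbind(x = rep(seq_len(nc), each = nr), y = rep(seq_len(nr), nc))
  fp <- .factor_pair(k)
  a <- fp[1]; b <- fp[2]   # a row-bands x b column-bands
  if (a > nr || b > nc) stop("infeasible layout: more domain tiles than grid cells")
  rband <- ceiling(a * coords[, "y"] / nr)
  cband <- ceiling(b * coords[, "x"] / nc)
  labels <- (rband - 1L) * b + cband
  list(coords = coords, labels = as.integer(labels))
}

.layout_blobs <- function(n, k) {
  ang <- 2 * pi * (seq_len(k) - 1) / k
  centers <- cbind(10 * cos(ang), 10 * sin(ang))
  labels <- rep(seq_len(k), length.out = n)
  labels <- labels[order(labels)]
  coords <- centers[labels, ] + matrix(stats::rnorm(2 * n, sd = 1.5), n, 2)
  colnames(coords) <- c("x", "y")
  list(coords = coords, labels = as.integer(labels))
}

.layout_stripes <- function(n, k) {
  coords <- cbind(x = stats::runif(n), y = stats::runif(n))
  br <- stats::quantile(coords[, "x"], probs = seq(0, 1, length.out = k + 1))
  labels <- as.integer(cut(coords[, "x"], breaks = br, labels = FALSE,
                           include.lowest = TRUE))
  list(coords = coords, labels = labels)
}

.factor_pair <- function(k) {
  a <- floor(sqrt(k))
  while (a > 1 && k %% a != 0) a <- a - 1
  c(a, k / a)
}
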