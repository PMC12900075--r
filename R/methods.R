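# S3 methods for fitted gatfuse models.

#' @method print gatfuse
#' @export
print.gatfuse <- function(x, ...) {
  cat("gatfuse fit:", nrow(x$embedding), "spots,",
      ncol(x$embedding), "latent dimensions\n")
  cat("  epochs:", nrow(x$log), " attention:", x$config$attention,
      " lambda:", paste(x$config$lambda, collapse = "/"), "\n")
  cat(sprintf("  final losses: recon1 %.4f  recon2 %.4f  cl %.4f (tau %.4g)\n",
              x$losses["recon1"], x$losses["recon2"], x$losses["cl"], x$tau))
  if (isTRUE(x$diverged)) cat("  NOTE: training diverged; last finite state\n")
  invisible(x)
}

#' Summarise a fitted model
#'
#' Reports the final losses, the training-loss trajectory endpoints and the
#' mean fusion attention weights at both levels.
#'
#' @param object a [gatfuse()] fit.
#' @param ... unused.
#' @return A list of class `summary.gatfuse`.
#' @method summary gatfuse
#' @export
summary.gatfuse <- function(object, ...) {
  aw <- object$attention_weights
  out <- list(
    n_spots = nrow(object$embedding),
    latent = ncol(object$embedding),
    epochs = nrow(object$log),
    losses = object$losses,
    first_total = object$log$total[1L],
    last_total = object$log$total[nrow(object$log)],
    tau = object$tau,
    mean_weights = list(intra_mod1 = colMeans(aw$intra_mod1),
                        intra_mod2 = colMeans(aw$intra_mod2),
                        cross = colMeans(aw$cross)),
    diverged = object$diverged)
  class(out) <- "summary.gatfuse"
  out
}

#' @method print summary.gatfuse
#' @export
print.summary.gatfuse <- function(x, ...) {
  cat("gatfuse fit summary\n")
  cat("  spots:", x$n_spots, " latent:", x$latent, " epochs:", x$epochs, "\n")
  cat(sprintf("  total loss: %.4f (epoch 1) -> %.4f (final)\n",
              x$first_total, x$last_total))
  cat(sprintf("  final: recon1 %.4f  recon2 %.4f  cl %.4f  tau %.4g\n",
              x$losses["recon1"], x$losses["recon2"], x$losses["cl"], x$tau))
  cat("  mean fusion weights:\n")
  for (nm in names(x$mean_weights)) {
    w <- x$mean_weights[[nm]]
    cat("    ", nm, ": ",
        paste(sprintf("%s %.3f", names(w), w), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Extract embeddings or domain assignments from a fit
#'
#' @param object a [gatfuse()] fit.
#' @param type `"embedding"` (the combined latent embedding, default),
#'   `"domains"` (cluster assignments of the embedding) or `"views"` (the
#'   four view embeddings).
#' @param n_clusters clusters for `type = "domains"`; defaults to the number
#'   of ground-truth domains when labels are present.
#' @param seed clustering seed.
#' @param ... passed to [cluster_embeddings()].
#' @return A matrix, an integer label vector, or a list of matrices.
#' @export
predict.gatfuse <- function(object, type = c("embedding", "domains", "views"),
                            n_clusters = NULL, seed = 0L, ...) {
  type <- match.arg(type)
  switch(type,
    embedding = object$embedding,
    views = object$views,
    domains = {
      if (is.null(n_clusters)) {
        if (is.null(object$labels))
          stop("n_clusters is required when the fit has no ground-truth labels")
        n_clusters <- nlevels(object$labels)
      }
      cluster_embeddings(object$embedding, n_clusters, seed = seed, ...)
    })
}

#' Reconstruction residuals
#'
#' @param object a [gatfuse()] fit.
#' @param modality 1, 2 or `"both"` (default: a list of both).
#' @param ... unused.
#' @return Residual matrix (input minus reconstruction) or a list of two.
#' @export
residuals.gatfuse <- function(object, modality = "both", ...) {
  r1 <- object$x1 - object$reconstructions$mod1
  r2 <- object$x2 - object$reconstructions$mod2
  if (identical(modality, 1) || identical(modality, "1")) return(r1)
  if (identical(modality, 2) || identical(modality, "2")) return(r2)
  list(mod1 = r1, mod2 = r2)
}

#' @export
fitted.gatfuse <- function(object, ...) object$reconstructions

#' Fusion attention weights of a fit
#'
#' The model's interpretable coefficients: per-spot convex weights over
#' (feature, spatial) views within each modality and over the two modalities
#' at the cross-modal level.
#'
#' @param object a [gatfuse()] fit.
#' @param ... unused.
#' @return List of three N x 2 matrices.
#' @export
coef.gatfuse <- function(object, ...) object$attention_weights

#' Plot a fitted model
#'
#' Scatter plot of the spot coordinates coloured by predicted domains
#' (default), ground-truth labels, or the cross-modal attention weight of
#' modality 1.
#'
#' @param x a [gatfuse()] fit.
#' @param what `"domains"`, `"truth"` or `"weight"`.
#' @param n_clusters clusters when `what = "domains"`.
#' @param seed clustering seed.
#' @param pch,cex usual graphical parameters.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the values used for colouring.
#' @export
plot.gatfuse <- function(x, what = c("domains", "truth", "weight"),
                         n_clusters = NULL, seed = 0L, pch = 16, cex = 0.7,
                         ...) {
  what <- match.arg(what)
  val <- switch(what,
    domains = factor(predict(x, "domains", n_clusters = n_clusters, seed = seed)),
    truth = {
      if (is.null(x$labels)) stop("fit has no ground-truth labels")
      x$labels
    },
    weight = x$attention_weights$cross[, 1L])
  if (is.factor(val)) {
    cols <- grDevices::hcl.colors(nlevels(val), "Dark 3")[as.integer(val)]
  } else {
    pal <- grDevices::hcl.colors(100, "Viridis")
    cols <- pal[cut(val, breaks = 100, labels = FALSE, include.lowest = TRUE)]
  }
  graphics::plot(x$coords, col = cols, pch = pch, cex = cex,
                 xlab = "x", ylab = "y",
                 main = paste("spatial", what), ...)
  invisible(val)
}
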