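# Loss assembly and the training loop.

small_pair <- function(seed = 0) {
  simulate_spatial_pair(n_spots = 80, n_domains = 2, f1 = 10, f2 = 8,
                        seed = seed)
}

small_fit <- function(pair, seed = 0, ...) {
  gatfuse(pair, k_feat = 6, k_spat = 6, hidden = 12, latent = 6,
          epochs = 25, seed = seed, ...)
}

test_that("reconstruction loss follows its definition", {
  x <- matrix(rnorm(12), 3, 4)
  expect_equal(reconstruction_loss(x, x), 0)
  expect_equal(reconstruction_loss(matrix(c(1, 1), 1, 2), matrix(0, 1, 2)), 2)
  set.seed(1)
  z <- matrix(rnorm(30), 5, 6)
  y <- matrix(rnorm(30), 5, 6)
  acc <- 0
  for (i in 1:5) for (j in 1:6) acc <- acc + (z[i, j] - y[i, j])^2
  expect_equal(reconstruction_loss(z, y), acc / 5, tolerance = 1e-12)
  expect_error(reconstruction_loss(z, y[, 1:3]), "dimensions differ")
})

test_that("total loss is the stated weighted sum", {
  expect_equal(total_loss(0.5, 0.25, 1, lambda = c(1, 2, 3)), 4.0)
  expect_equal(total_loss(0, 0, 0), 0)
  expect_equal(total_loss(1, 2, 99, lambda = c(1, 1, 0)), 3)
  expect_error(total_loss(1, 1, 1, lambda = c(0, 0, 0)))
  expect_error(total_loss(NaN, 0, 0))
})

test_that("training is deterministic: same seed, identical fits", {
  pair <- small_pair()
  f1 <- small_fit(pair, seed = 42)
  f2 <- small_fit(pair, seed = 42)
  expect_identical(f1$embedding, f2$embedding)
  expect_identical(f1$log, f2$log)
  f3 <- small_fit(pair, seed = 43)
  expect_false(identical(f1$embedding, f3$embedding))
})

test_that("fitting does not disturb the caller's RNG stream", {
  pair <- small_pair()
  set.seed(7); before <- rnorm(3)
  set.seed(7); invisible(small_fit(pair)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("the full and no-CL runs share their first forward pass", {
  pair <- small_pair()
  full <- small_fit(pair, seed = 5)
  nocl <- small_fit(pair, seed = 5, lambda = c(1, 1, 0))
  expect_equal(full$log$loss_recon1[1], nocl$log$loss_recon1[1],
               tolerance = 1e-12)
  expect_equal(full$log$loss_recon2[1], nocl$log$loss_recon2[1],
               tolerance = 1e-12)
  expect_equal(nocl$log$loss_cl[1], 0)
})

test_that("training reduces the loss and logs every epoch", {
  pair <- small_pair()
  fit <- small_fit(pair)
  expect_equal(nrow(fit$log), 25L)
  expect_named(fit$log, c("step", "loss_recon1", "loss_recon2", "loss_cl",
                          "tau", "total"))
  expect_lt(fit$log$total[25], fit$log$total[1])
  expect_false(fit$diverged)
})

test_that("the fit object exposes coherent components", {
  pair <- small_pair()
  fit <- small_fit(pair)
  expect_s3_class(fit, "gatfuse")
  expect_equal(dim(fit$embedding), c(80L, 6L))
  expect_equal(rownames(fit$embedding), pair$spot_ids)
  expect_named(fit$views, c("f1", "s1", "f2", "s2"))
  expect_equal(dim(fit$reconstructions$mod1), dim(pair$x1))
  aw <- fit$attention_weights
  expect_equal(unname(rowSums(aw$intra_mod1)), rep(1, 80), tolerance = 1e-6)
  expect_equal(unname(rowSums(aw$cross)), rep(1, 80), tolerance = 1e-6)
  expect_true(all(is.finite(fit$losses)))
  expect_output(print(fit), "80 spots")
  expect_output(print(summary(fit)), "total loss")
})

test_that("the trained temperature follows the annealing schedule", {
  pair <- small_pair()
  fit <- gatfuse(pair, k_feat = 6, k_spat = 6, hidden = 10, latent = 5,
                 epochs = 120, seed = 0,
                 contrastive = contrastive_config(tau = 0.5,
                                                  anneal_factor = 0.9,
                                                  anneal_every = 50))
  # anneals at steps 50 and 100
  expect_equal(fit$tau, 0.5 * 0.9^2, tolerance = 1e-12)
  expect_equal(fit$log$tau[1], 0.5)
  expect_equal(fit$log$tau[60], 0.45, tolerance = 1e-12)
})

test_that("learnable tau changes by gradient and respects the floor", {
  pair <- small_pair()
  fit <- small_fit(pair, learnable_tau = TRUE)
  expect_true(fit$tau >= 1e-3)
  expect_false(isTRUE(all.equal(fit$tau, 0.5 * 0.9^0)))  # moved off tau0
})

test_that("S3 methods return the advertised quantities", {
  pair <- small_pair()
  fit <- small_fit(pair)
  expect_identical(predict(fit), fit$embedding)
  dom <- predict(fit, "domains")
  expect_length(dom, 80)
  expect_equal(sort(unique(dom)), 1:2)
  expect_identical(coef(fit), fit$attention_weights)
  r <- residuals(fit, modality = 1)
  expect_equal(r, pair$x1 - fit$reconstructions$mod1)
  expect_identical(fitted(fit), fit$reconstructions)
  pdf(NULL)
  on.exit(dev.off(), add = TRUE)
  expect_silent(plot(fit, what = "truth"))
})

test_that("checkpoints round-trip with a validated manifest", {
  pair <- small_pair()
  fit <- small_fit(pair)
  path <- withr::local_tempfile(fileext = ".rds")
  save_gatfuse(fit, path)
  back <- load_gatfuse(path)
  expect_identical(back$embedding, fit$embedding)
  expect_identical(back$manifest$config_hash, fit$manifest$config_hash)
  # a tampered config no longer matches its manifest hash
  bad <- fit
  bad$config$lr <- 99
  bad_path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(bad, bad_path)
  expect_error(load_gatfuse(bad_path), "manifest")
  expect_error(load_gatfuse(withr::local_tempfile(fileext = ".rds",
                                                  lines = "")))
})

test_that("run_ablation produces the documented table on a small instance", {
  pair <- small_pair()
  tab <- run_ablation(pair, seeds = 0, k_feat = 6, k_spat = 6,
                      hidden = 12, latent = 6, epochs = 15)
  expect_equal(nrow(tab), 3L)
  expect_setequal(tab$variant, c("full", "no_cl", "no_gat"))
  expect_true(is.na(tab$loss_cl[tab$variant == "no_cl"]))
  expect_false(anyNA(tab$ari))
  summ <- attr(tab, "summary")
  expect_equal(nrow(summ), 3L)
  expect_error(run_ablation(pair, variants = "bogus"), "unknown variant")
  unlabeled <- spatial_omics_pair(pair$x1, pair$x2, pair$coords)
  expect_error(run_ablation(unlabeled), "labels")
})

test_that("the uniform-attention ablation exports exactly uniform weights", {
  pair <- small_pair()
  fit <- small_fit(pair, attention = "uniform")
  g <- fit$graphs$f1
  att <- gat_attention(pair$x1, g, fit$model$enc$f1$layers[[1]],
                       mode = "uniform")
  deg <- table(att$i)
  expect_equal(unname(att$alpha[, 1]),
               unname(1 / as.vector(deg)[att$i]), tolerance = 1e-12)
})
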