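test_that("autoencoder reaches the reconstruction target on a mixed corpus", {
  cae <- cae_500()
  expect_lte(cae$held_out_mse, cae$spec$mse_threshold)
  expect_gte(cae$best_epoch, 1)
})

test_that("encoder and decoder satisfy the shape contract for all inputs", {
  cae <- cae_500()
  for (s in c(2, 3, 4)) {
    set.seed(s)
    m <- generate_matrix("random", s)
    z <- encode(cae, expand_matrix(m))
    expect_equal(dim(z), c(1, 8))
    expect_true(all(is.finite(z)))
    rec <- decode(cae, as.vector(z))[[1]]
    expect_equal(dim(rec), c(12, 12, 12))
  }
})

test_that("decoded matrices are always valid porosity matrices", {
  cae <- cae_500()
  set.seed(7)
  z <- matrix(rnorm(20 * 8, sd = 2), 20, 8)
  mats <- decode_to_matrix(z, cae, snap = FALSE)
  for (m in mats) {
    expect_s3_class(m, "porosity_matrix")
    expect_gte(min(m), 0.2)
    expect_lte(max(m), 0.9)
  }
  snapped <- decode_to_matrix(z, cae, snap = TRUE)
  for (m in snapped)
    expect_true(all(abs(as.vector(m) * 10 - round(as.vector(m) * 10)) < 1e-9))
  expect_error(decode_to_matrix(rnorm(5), cae), "latent dimension")
})

test_that("encoding a uniform design round-trips through the latent space", {
  cae <- cae_500()
  x <- expand_matrix(porosity_matrix(array(0.5, c(3, 3, 3))))
  z <- encode(cae, x)
  m <- decode_to_matrix(as.vector(z), cae, snap = FALSE)
  expect_equal(mean(m), 0.5, tolerance = 0.05)
})

test_that("reconstruction loss decreases over early epochs in seeded runs", {
  cc <- corpus_500()
  X <- cc$arrays[, seq_len(110)]
  drops <- 0L
  for (s in 1:10) {
    fit <- suppressWarnings(
      train_cae(X, cae_spec(epochs = 5, seed = s, val_frac = 0)))
    if (all(diff(fit$train_mse) < 0)) drops <- drops + 1L
  }
  expect_gte(drops, 8L)
})

test_that("mixture selection recovers the generating component count", {
  k1 <- 0L
  for (s in 1:10) {
    set.seed(s)
    emb <- matrix(rnorm(300 * 8), 300, 8)
    if (fit_latent_gmm(emb, K_range = 1:3, seed = s)$K == 1) k1 <- k1 + 1L
  }
  expect_gte(k1, 9L)
  set.seed(41)
  emb2 <- rbind(matrix(rnorm(150 * 8, -5), 150, 8),
                matrix(rnorm(150 * 8, 5), 150, 8))
  g2 <- fit_latent_gmm(emb2, K_range = 1:3, seed = 1)
  expect_equal(g2$K, 2L)
  expect_equal(sum(g2$weights), 1, tolerance = 1e-9)
  for (k in seq_len(g2$K))
    expect_true(all(eigen(g2$covariances[, , k])$values > 0))
})

test_that("degenerate embeddings are rejected", {
  emb <- cbind(matrix(rnorm(200 * 7), 200, 7), 0)
  expect_error(fit_latent_gmm(emb, K_range = 1:2), "zero variance")
})

test_that("latent sampling is sized, seeded and statistically consistent", {
  set.seed(1)
  emb <- matrix(rnorm(400 * 8, sd = 2), 400, 8)
  gmm <- fit_latent_gmm(emb, K_range = 1:2, seed = 3)
  s1 <- sample_latent(gmm, 2000, seed = 9)
  expect_equal(dim(s1), c(2000, 8))
  expect_identical(s1, sample_latent(gmm, 2000, seed = 9))
  big <- sample_latent(gmm, 5000, seed = 11)
  se <- apply(big, 2, stats::sd) / sqrt(5000)
  expect_true(all(abs(colMeans(big) - gmm_mean(gmm)) <= 3 * se + 1e-8))
})
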