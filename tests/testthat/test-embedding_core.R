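fuse_random <- function(n, seed, T = 5, K = 4) {
  set.seed(seed)
  X1 <- matrix(rnorm(n * 4), n, 4)
  X2 <- matrix(rnorm(n * 4), n, 4)
  rownames(X1) <- rownames(X2) <- sprintf("s%02d", seq_len(n))
  p <- snf_params(K = K, T = T)
  snf_fuse(list(modality_affinity(X1, p), modality_affinity(X2, p)), p)
}

test_that("embedding matches the dense eigendecomposition oracle", {
  for (s in 1:5) {
    f <- fuse_random(12, seed = s)
    emb <- diffusion_map_embed(f, embedding_params(n_components = 4))
    ora <- naive_diffusion_embed(unclass(f), 4)
    expect_equal(emb$scores, ora$scores, ignore_attr = TRUE,
                 tolerance = 1e-8)
    expect_equal(emb$eigenvalues, ora$eigenvalues, tolerance = 1e-8)
    expect_true(all(diff(emb$eigenvalues) < 0))
    expect_true(all(emb$eigenvalues > 0 & emb$eigenvalues < 1))
  }
})

test_that("first component separates a two-block network by sign", {
  blocks <- rep(c(1, 2), each = 6)
  S <- matrix(0.01, 12, 12)
  S[outer(blocks, blocks, "==")] <- 1
  rownames(S) <- colnames(S) <- sprintf("s%02d", 1:12)
  emb <- diffusion_map_embed(S, embedding_params(n_components = 2))
  s1 <- emb$scores[, 1]
  expect_true(all(sign(s1[blocks == 1]) == sign(s1[1])))
  expect_true(all(sign(s1[blocks == 2]) == -sign(s1[1])))
})

test_that("embedding is permutation-equivariant and scale-invariant", {
  f <- fuse_random(15, seed = 8)
  emb <- diffusion_map_embed(f, embedding_params(n_components = 3))
  set.seed(1)
  perm <- sample(15)
  fp <- unclass(f)[perm, perm]
  embp <- diffusion_map_embed(fp, embedding_params(n_components = 3))
  expect_equal(embp$scores, emb$scores[perm, ], ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_equal(embp$eigenvalues, emb$eigenvalues, tolerance = 1e-10)
  embc <- diffusion_map_embed(unclass(f) * 17.3,
                              embedding_params(n_components = 3))
  expect_equal(embc$scores, emb$scores, ignore_attr = TRUE,
               tolerance = 1e-8)
})

test_that("disconnected similarity graphs are rejected", {
  S <- matrix(0, 8, 8)
  S[1:4, 1:4] <- 0.9
  S[5:8, 5:8] <- 0.9
  diag(S) <- 1
  expect_error(diffusion_map_embed(S, embedding_params(n_components = 2)),
               "disconnected")
})

test_that("noise-free rank-one cohort embeds onto the planted axis", {
  cfg <- generator_config(n_subjects = 80, n_modalities = 1, noise_sd = 0,
                          sex_gradient_strength = 0, pds_coupling = 0,
                          seed = 21)
  co <- generate_cohort(cfg)
  fe <- fuse_and_embed(co$modalities$single, snf_params(K = 10),
                       embedding_params(n_components = 2))
  # the diffusion coordinate of a 1-D manifold is monotone in the latent but
  # intrinsically curved (cosine-like), so rank agreement is near-perfect
  # while the linear correlation plateaus below it
  expect_gt(abs(cor(fe$embedding$scores[, 1], co$latent$z,
                    method = "spearman")), 0.995)
  expect_gt(abs(cor(fe$embedding$scores[, 1], co$latent$z)), 0.9)
})

test_that("Procrustes alignment recovers sign flips and rotations", {
  set.seed(2)
  A <- matrix(rnorm(20), 20, 1)
  expect_equal(procrustes_align(A, -A), -A, tolerance = 1e-12,
               ignore_attr = TRUE)
  A3 <- matrix(rnorm(60), 20, 3)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  B <- A3 %*% R
  expect_lt(sqrt(sum((procrustes_align(A3, B) - B) ^ 2)), 1e-10)
  # alignment never increases the Frobenius residual
  N <- matrix(rnorm(60), 20, 3)
  resid_aligned <- sum((procrustes_align(A3, N) - N) ^ 2)
  ctr <- function(M) sweep(M, 2, colMeans(M))
  resid_raw <- sum((ctr(A3) + rep(colMeans(N), each = 20) - N) ^ 2)
  expect_lte(resid_aligned, resid_raw + 1e-12)
  expect_error(procrustes_align(A3, A), "shape")
})

test_that("Procrustes with scaling matches magnitudes for one component", {
  set.seed(3)
  y <- rnorm(30)
  pred <- -2.5 * y + rnorm(30, sd = 0.01)
  al <- procrustes_align(matrix(pred), matrix(y), scale = TRUE)
  expect_gt(cor(al, y), 0.99)
  expect_equal(sd(al) / sd(y), 1, tolerance = 0.05)
})

test_that("embedding comparison metrics match hand arithmetic", {
  y <- c(1, 2, 3, 4, 10)
  cmp0 <- compare_embeddings(y, y)
  expect_equal(unclass(cmp0)[c("rmse", "mae", "r2", "pearson_r")],
               list(rmse = 0, mae = 0, r2 = 1, pearson_r = 1))
  cmp1 <- compare_embeddings(y + 1, y)
  expect_equal(cmp1$mae, 1)
  expect_equal(cmp1$rmse, 1)
  expect_equal(cmp1$pearson_r, 1)
  p <- c(1.5, 2.5, 2, 5, 9)
  cmp <- compare_embeddings(p, y)
  e <- p - y
  expect_equal(cmp$rmse, sqrt(mean(e ^ 2)))
  expect_equal(cmp$mae, mean(abs(e)))
  expect_equal(cmp$r2, 1 - sum(e ^ 2) / sum((y - mean(y)) ^ 2))
  expect_gte(cmp$rmse, cmp$mae)
  expect_error(compare_embeddings(p, rep(1, 5)), "zero variance")
})

test_that("feature loadings are correlations with the stated edge cases", {
  set.seed(4)
  score <- rnorm(50)
  X <- cbind(exact = score, flat = rep(1, 50),
             affine = 3 - 2 * score, noise = rnorm(50))
  ld <- feature_loadings(X, score)
  expect_equal(unname(ld["exact"]), 1)
  expect_true(is.na(ld["flat"]))
  expect_equal(unname(ld["affine"]), -1)
  # independent noise at large n has small loadings
  set.seed(5)
  s2 <- rnorm(2000)
  ld2 <- feature_loadings(matrix(rnorm(2000 * 5), 2000, 5), s2)
  expect_true(all(abs(ld2) < 0.1))
})
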