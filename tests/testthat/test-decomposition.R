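# PCA/ICA of the effect matrix, scree, alignment, conventions.

test_that("pca_decompose: rank-1 input, full-rank reconstruction, oracle spectrum", {
  u <- c(1, -2, 3); v <- rnorm(7)
  d1 <- pca_decompose(outer(u, v), 1)
  expect_equal(d1$variance_explained, 1.0, tolerance = 1e-12)

  X <- matrix(rnorm(8 * 15), 8, 15)
  dfull <- pca_decompose(X, 8)
  expect_equal(dfull$trait_loadings %*% dfull$snp_loadings, X,
               ignore_attr = TRUE, tolerance = 1e-8)

  set.seed(3)
  X2 <- matrix(rnorm(20 * 50), 20, 50)
  d5 <- pca_decompose(X2, 5)
  # independent oracle: eigenvalues of the uncentered Gram matrix
  ev <- eigen(tcrossprod(X2), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(d5$variance_explained, (ev / sum(ev))[1:5], tolerance = 1e-10)
  # orthonormal snp-loading rows
  expect_equal(tcrossprod(d5$snp_loadings), diag(5),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_error(pca_decompose(X2, 21), "K must be")
})

test_that("ica_decompose recovers planted super-Gaussian sources exactly (noiseless)", {
  set.seed(11)
  n <- 2000L; K <- 3L; m <- 12L
  # independent Laplacian rows
  S <- matrix(stats::rexp(K * n) * sign(rnorm(K * n)), K, n)
  A <- matrix(rnorm(m * K), m, K)
  X <- A %*% S
  d <- ica_decompose(X, K, seed = 5)
  R <- abs(cor(t(d$snp_loadings), t(S)))
  # best match per true source, found via the alignment machinery
  best <- apply(R, 2, max)
  expect_true(all(best > 0.999))
  # reconstruction equals the rank-K PCA approximation (here: X itself)
  expect_equal(d$trait_loadings %*% d$snp_loadings, X,
               ignore_attr = TRUE, tolerance = 1e-6)
  # unit-RMS snp-loading rows
  expect_equal(rowMeans(d$snp_loadings^2), rep(1, K),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("ica on Gaussian input converges or errors cleanly, never NaN", {
  set.seed(21)
  X <- matrix(rnorm(10 * 400), 10, 400)
  res <- tryCatch(ica_decompose(X, 2, seed = 3), error = function(e) e)
  if (inherits(res, "error")) {
    expect_s3_class(res, "gwasdecomp_convergence_error")
  } else {
    expect_false(any(!is.finite(res$snp_loadings)))
    expect_equal(res$variance_explained, pca_decompose(X, 2)$variance_explained,
                 tolerance = 1e-12)
  }
  expect_error(ica_decompose(X, 1, seed = 1), "K >= 2")
})

test_that("permuting SNP columns permutes snp_loadings and leaves trait loadings", {
  set.seed(13)
  n <- 500L
  S <- matrix(rnorm(3 * n)^3, 3, n)  # skewed, well-identified
  A <- matrix(rnorm(15 * 3), 15, 3)
  X <- A %*% S
  colnames(X) <- sprintf("rs%04d", seq_len(n))
  perm <- sample.int(n)
  d1 <- ica_decompose(X, 3, seed = 9, tol = 1e-10)
  d2 <- ica_decompose(X[, perm], 3, seed = 9, tol = 1e-10)
  expect_equal(d2$snp_loadings[, order(perm)], d1$snp_loadings,
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(d2$trait_loadings, d1$trait_loadings,
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("scree_table yields cumulative spectrum fractions", {
  # equal singular values: orthogonal design
  X <- diag(100)
  d <- pca_decompose(X, 5)
  expect_equal(scree_table(d, 5)$cumulative_variance, 0.05, tolerance = 1e-10)
  expect_equal(scree_table(d, 100)$cumulative_variance, 1.0, tolerance = 1e-12)

  set.seed(2)
  X2 <- matrix(rnorm(10 * 30), 10, 30)
  d2 <- pca_decompose(X2, 3)
  sv <- svd(X2)$d
  expect_equal(scree_table(d2, 1:3)$cumulative_variance,
               (cumsum(sv^2) / sum(sv^2))[1:3], tolerance = 1e-10)
  expect_error(scree_table(d2, 11), "spectrum")
})

test_that("align_components inverts permutations and sign flips", {
  set.seed(7)
  em <- random_effect_matrix(12, 200, seed = 7)
  a <- pca_decompose(em, 4)
  b <- a
  perm <- c(3, 1, 4, 2); flip <- c(1, -1, -1, 1)
  b$snp_loadings <- diag(flip) %*% a$snp_loadings[perm, ]
  colnames(b$snp_loadings) <- colnames(a$snp_loadings)
  pr <- align_components(a, b)
  expect_equal(pr$index_b, order(perm))
  expect_equal(abs(pr$r), rep(1, 4), tolerance = 1e-12)
  expect_equal(pr$sign, flip[order(perm)] * 1)

  a1 <- pca_decompose(em, 1); b1 <- pca_decompose(em, 1)
  pr1 <- align_components(a1, b1)
  expect_equal(nrow(pr1), 1L)
  expect_equal(pr1$r, 1, tolerance = 1e-12)
})

test_that("alignment total |r| equals brute-force permutation search", {
  set.seed(17)
  for (K in c(3, 4)) {
    a <- pca_decompose(matrix(rnorm(10 * 100), 10, 100), K)
    b <- pca_decompose(matrix(rnorm(10 * 100), 10, 100), K)
    colnames(b$snp_loadings) <- colnames(a$snp_loadings)
    pr <- align_components(a, b)
    R <- abs(cor(t(a$snp_loadings), t(b$snp_loadings)))
    perms <- as.matrix(expand.grid(rep(list(seq_len(K)), K)))
    perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), , drop = FALSE]
    best <- max(apply(perms, 1, function(p) sum(R[cbind(seq_len(K), p)])))
    expect_equal(sum(abs(pr$r)), best, tolerance = 1e-12)
  }
})

test_that("fixed seeds reproduce bit-identically; seeds agree after alignment", {
  set.seed(23)
  S <- matrix(rnorm(4 * 800)^3, 4, 800)
  A <- matrix(rnorm(20 * 4), 20, 4)
  X <- A %*% S + 0.01 * matrix(rnorm(20 * 800), 20, 800)
  d1 <- ica_decompose(X, 4, seed = 100)
  d2 <- ica_decompose(X, 4, seed = 100)
  expect_identical(d1$snp_loadings, d2$snp_loadings)
  expect_identical(d1$trait_loadings, d2$trait_loadings)

  d3 <- ica_decompose(X, 4, seed = 200)
  pr <- align_components(d1, d3)
  expect_true(all(abs(pr$r) > 0.99))
})

test_that("no demeaning: a constant added to one SNP column shifts the result", {
  set.seed(29)
  X <- matrix(rnorm(10 * 60), 10, 60)
  d0 <- pca_decompose(X, 3)
  X1 <- X; X1[, 5] <- X1[, 5] + 10
  d1 <- pca_decompose(X1, 3)
  # the offset must NOT be removed: loadings respond to it
  expect_gt(max(abs(abs(d1$snp_loadings[1, ]) - abs(d0$snp_loadings[1, ]))), 0.01)
  # and the rank-K reconstruction tracks the shifted matrix, not the centred one
  expect_gt(abs(mean((d1$trait_loadings %*% d1$snp_loadings)[, 5]) -
                mean((d0$trait_loadings %*% d0$snp_loadings)[, 5])), 1)
})

test_that("no variance normalization: scaling one SNP column scales its influence", {
  set.seed(31)
  X <- matrix(rnorm(8 * 40), 8, 40)
  c_scale <- 50
  X2 <- X; X2[, 7] <- X2[, 7] * c_scale
  d0 <- pca_decompose(X, 1); d2 <- pca_decompose(X2, 1)
  w0 <- abs(d0$snp_loadings[1, 7]); w2 <- abs(d2$snp_loadings[1, 7])
  # the scaled column comes to dominate the first component
  expect_gt(w2, 0.9)
  expect_lt(w0, 0.6)
})

test_that("PCA and ICA share the singular spectrum and variance explained", {
  set.seed(37)
  S <- matrix(rnorm(3 * 500)^3, 3, 500)
  X <- matrix(rnorm(9 * 3), 9, 3) %*% S
  p <- pca_decompose(X, 3)
  i <- ica_decompose(X, 3, seed = 2)
  expect_equal(i$singular_spectrum, p$singular_spectrum, tolerance = 1e-12)
  expect_equal(i$variance_explained, p$variance_explained, tolerance = 1e-12)
})

test_that("snp-loading rows carry the skewness-positive sign convention", {
  set.seed(41)
  S <- matrix(rexp(3 * 600) * sign(runif(3 * 600) < 0.8) , 3, 600)
  X <- matrix(rnorm(10 * 3), 10, 3) %*% S
  for (d in list(pca_decompose(X, 3), ica_decompose(X, 3, seed = 4))) {
    sk <- apply(d$snp_loadings, 1, function(x) mean((x - mean(x))^3) / sd(x)^3)
    expect_true(all(sk > 0))
  }
})

test_that("decomposition files are written and carry the seed fingerprint", {
  set.seed(43)
  S <- matrix(rnorm(3 * 50)^3, 3, 50)
  em <- random_effect_matrix(8, 50, seed = 43)
  em$values <- matrix(rnorm(8 * 3), 8, 3) %*% S
  dimnames(em$values) <- list(em$trait_ids, em$snp_registry$snp_id)
  d <- ica_decompose(em, 3, seed = 77)
  pre <- file.path(withr::local_tempdir(), "dec")
  files <- write_decomposition(d, pre)
  expect_true(all(file.exists(files)))
  meta <- jsonlite::read_json(paste0(pre, "_meta.json"))
  expect_equal(meta$seed, 77)
  expect_equal(meta$method, "ica")
})
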