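# Two-dimensional t-SNE embedding of trait loadings, to visualise how
# traits (e.g. imaging modalities) cluster by their shared genomic
# factors. Exact (dense) t-SNE: trait counts are at most a few thousand,
# so the O(m^2) formulation is adequate and keeps the embedding fully
# deterministic for a fixed seed.

# Conditional Gaussian affinities with per-point bandwidth calibrated to
# the target perplexity by bisection on log-precision.
tsne_affinities <- function(D2, perplexity, tol = 1e-5, max_tries = 50L) {
  m <- nrow(D2)
  P <- matrix(0, m, m)
  logU <- log(perplexity)
  for (i in seq_len(m)) {
    beta <- 1; beta_min <- -Inf; beta_max <- Inf
    di <- D2[i, -i]
    for (tr in seq_len(max_tries)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { H <- 0; p <- w }
      else {
        p <- w / sw
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) { beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else { beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * m)
  pmax(P, .Machine$double.xmin)
}

tsne_run <- function(X, perplexity, max_iter = 500L, eta = 200,
                     exaggeration = 4, exag_iter = 100L) {
  m <- nrow(X)
  sumX <- rowSums(X^2)
  D2 <- pmax(outer(sumX, sumX, "+") - 2 * tcrossprod(X), 0)
  P <- tsne_affinities(D2, perplexity)
  Y <- matrix(stats::rnorm(m * 2, sd = 1e-4), m, 2)
  dY <- matrix(0, m, 2); gains <- matrix(1, m, 2)
  for (it in seq_len(max_iter)) {
    Pit <- if (it <= exag_iter) P * exaggeration else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + pmax(outer(sumY, sumY, "+") - 2 * tcrossprod(Y), 0))
    diag(num) <- 0
    Q <- pmax(num / sum(num), .Machine$double.xmin)
    L <- (Pit - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (it <= 250L) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Embed trait loadings in two dimensions with t-SNE
#'
#' Deterministic (seeded) t-distributed stochastic neighbour embedding of
#' the m x K trait-loading matrix, used to visualise clustering of traits
#' by their genomic-component profiles.
#'
#' @param A Trait-loading matrix (m x K) or a `decomposition`.
#' @param perplexity Effective neighbourhood size; requires
#'   `m > 3 * perplexity`.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param modality_labels Optional per-trait category labels carried
#'   through to the result.
#' @param max_iter Gradient-descent iterations (default 500).
#' @return An `embedding_result`: `coords` (m x 2), `trait_ids`,
#'   `modality_labels`, `perplexity`, `seed`.
#' @export
embed_trait_loadings <- function(A, perplexity = 30, seed = 1L,
                                 modality_labels = NULL, max_iter = 500L) {
  if (inherits(A, "decomposition")) {
    trait_ids <- A$trait_ids
    A <- A$trait_loadings
  } else {
    A <- as.matrix(A)
    trait_ids <- rownames(A) %||% paste0("trait", seq_len(nrow(A)))
  }
  m <- nrow(A)
  if (ncol(A) < 2L) stop_domain("need at least 2 components to embed")
  if (m <= 3 * perplexity) {
    stop_domain("perplexity too large: need m > 3 * perplexity (m = ", m, ")")
  }
  if (!is.null(modality_labels) && length(modality_labels) != m) {
    stop_domain("modality_labels length must equal the number of traits")
  }
  set.seed(seed)
  Y <- tsne_run(A, perplexity, max_iter = max_iter)
  if (any(!is.finite(Y))) stop_domain("embedding diverged to non-finite coordinates")
  dimnames(Y) <- list(trait_ids, c("dim1", "dim2"))
  structure(list(coords = Y, trait_ids = trait_ids,
                 modality_labels = modality_labels,
                 perplexity = perplexity, seed = seed),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("t-SNE embedding: %d traits, perplexity %.1f, seed %d\n",
              nrow(x$coords), x$perplexity, x$seed))
  invisible(x)
}

#' Write embedding coordinates to TSV
#'
#' @param emb An `embedding_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(emb, path) {
  out <- data.frame(trait_id = emb$trait_ids,
                    dim1 = format_full(emb$coords[, 1]),
                    dim2 = format_full(emb$coords[, 2]),
                    stringsAsFactors = FALSE)
  if (!is.null(emb$modality_labels)) out$modality <- emb$modality_labels
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
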