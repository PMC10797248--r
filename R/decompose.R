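# PCA and ICA of the traits-by-SNPs effect matrix along the SNP dimension.
#
# Deliberately NO centering and NO per-SNP variance normalisation: GWAS
# effect sizes are centred on zero under the null (effect-allele direction
# is arbitrary), and the magnitude of allelic effects carries biological
# information that variance normalisation would destroy. Both behaviours
# are asserted by tests.

new_decomposition <- function(method, K, snp_loadings, trait_loadings,
                              trait_ids, snp_registry, singular_spectrum,
                              variance_explained, config) {
  rownames(snp_loadings) <- paste0(if (method == "pca") "PC" else "IC", seq_len(K))
  colnames(trait_loadings) <- rownames(snp_loadings)
  rownames(trait_loadings) <- trait_ids
  structure(list(method = method, K = K,
                 snp_loadings = snp_loadings,
                 trait_loadings = trait_loadings,
                 trait_ids = trait_ids,
                 snp_registry = snp_registry,
                 singular_spectrum = singular_spectrum,
                 variance_explained = variance_explained,
                 config = config),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("%s decomposition: K = %d (%d traits x %d SNPs), variance explained = %.1f%%\n",
              toupper(x$method), x$K, nrow(x$trait_loadings),
              ncol(x$snp_loadings), 100 * sum(x$variance_explained)))
  invisible(x)
}

as_values <- function(X) {
  if (inherits(X, "effect_matrix")) X$values else as.matrix(X)
}

as_registry <- function(X) {
  if (inherits(X, "effect_matrix")) return(X$snp_registry)
  ids <- colnames(as.matrix(X)) %||% paste0("snp", seq_len(ncol(as.matrix(X))))
  data.frame(snp_id = ids, chrom = NA_character_, pos = NA_integer_,
             effect_allele = NA_character_, stringsAsFactors = FALSE)
}

check_K <- function(K, m, n) {
  if (!(length(K) == 1L && K == round(K) && K >= 1 && K <= min(m, n))) {
    stop_domain("K must be an integer in [1, min(m, n)] = [1, ", min(m, n), "]")
  }
  as.integer(K)
}

# Skewness-positive sign convention applied jointly to a snp-loading row
# and its trait-loading column; falls back to making the largest-|value|
# entry positive when skewness is numerically zero.
fix_signs <- function(S, A) {
  for (k in seq_len(nrow(S))) {
    sk <- row_skewness(S[k, ])
    flip <- if (abs(sk) > 1e-12) sk < 0 else S[k, which.max(abs(S[k, ]))] < 0
    if (flip) { S[k, ] <- -S[k, ]; A[, k] <- -A[, k] }
  }
  list(S = S, A = A)
}

#' Principal genomic components of an effect matrix
#'
#' Uncentered singular value decomposition of the m x n effect matrix.
#' SNP loadings are the top-K right singular vectors (orthonormal rows,
#' skewness-positive sign); trait loadings carry the singular values so
#' that `trait_loadings %*% snp_loadings` is the rank-K approximation of
#' the input. Variance explained is \eqn{\sigma_k^2 / \sum_i \sigma_i^2}.
#'
#' @param X An [effect_matrix()] or plain numeric matrix (traits in rows).
#' @param K Number of components, `1 <= K <= min(m, n)`.
#' @return A `decomposition` object.
#' @export
pca_decompose <- function(X, K) {
  V <- as_values(X)
  if (any(!is.finite(V))) stop_domain("effect matrix has non-finite entries")
  K <- check_K(K, nrow(V), ncol(V))
  sv <- svd(V)
  ve <- sv$d^2 / sum(sv$d^2)
  S <- t(sv$v[, seq_len(K), drop = FALSE])
  A <- sv$u[, seq_len(K), drop = FALSE] %*% diag(sv$d[seq_len(K)], K, K)
  fx <- fix_signs(S, A)
  colnames(fx$S) <- colnames(V) %||% as_registry(X)$snp_id
  new_decomposition("pca", K, fx$S, fx$A,
                    rownames(V) %||% paste0("trait", seq_len(nrow(V))),
                    as_registry(X), sv$d, ve[seq_len(K)],
                    list(method = "pca", K = K, centered = FALSE,
                         variance_normalized = FALSE))
}

sym_decorrelate <- function(W) {
  s <- svd(W)
  s$u %*% t(s$v)
}

# Fixed-point FastICA iteration with log-cosh (tanh) contrast and
# symmetric decorrelation on pre-whitened data Z (K x n, unit row RMS).
fastica_core <- function(Z, K, seed, tol, max_iter, alpha = 1) {
  n <- ncol(Z)
  set.seed(seed)
  W <- sym_decorrelate(matrix(stats::rnorm(K * K), K, K))
  for (it in seq_len(max_iter)) {
    U <- W %*% Z
    G <- tanh(alpha * U)
    W1 <- (G %*% t(Z)) / n - diag(alpha * rowMeans(1 - G^2), K, K) %*% W
    if (any(!is.finite(W1))) return(list(converged = FALSE, iter = it, delta = NA_real_))
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) return(list(converged = TRUE, W = W, iter = it, delta = delta))
  }
  list(converged = FALSE, W = W, iter = max_iter, delta = delta)
}

#' Independent genomic components of an effect matrix
#'
#' MELODIC-style ICA along the SNP dimension: the matrix is whitened in
#' its K-dimensional (uncentered) principal subspace, then rotated by
#' fixed-point iteration maximising non-Gaussianity (log-cosh contrast,
#' symmetric decorrelation) until convergence. SNP-loading rows are scaled
#' to unit root-mean-square; trait loadings absorb scale and rotation so
#' `trait_loadings %*% snp_loadings` equals the rank-K PCA approximation.
#' Components are ordered by decreasing explained energy (squared norm of
#' the trait-loading column) with skewness-positive signs; the singular
#' spectrum and variance-explained values are those of the PCA subspace
#' (ICA is a rotation within it).
#'
#' @param X An [effect_matrix()] or numeric matrix (traits in rows).
#' @param K Number of components (>= 2; a one-dimensional "unmixing" is
#'   degenerate).
#' @param seed Integer seed for the random orthogonal start; fixed seed
#'   gives bit-identical output.
#' @param tol Per-component convergence tolerance on
#'   `1 - |<w_new, w_old>|`.
#' @param max_iter Maximum fixed-point iterations per restart.
#' @param restarts Random restarts attempted on non-convergence before a
#'   convergence error is raised.
#' @return A `decomposition` object.
#' @export
ica_decompose <- function(X, K, seed = 1L, tol = 1e-6, max_iter = 1000L,
                          restarts = 5L) {
  V <- as_values(X)
  if (any(!is.finite(V))) stop_domain("effect matrix has non-finite entries")
  K <- check_K(K, nrow(V), ncol(V))
  if (K < 2L) stop_domain("ICA needs K >= 2: a single component cannot be unmixed")
  m <- nrow(V); n <- ncol(V)
  sv <- svd(V)
  if (sv$d[K] <= sv$d[1] * 1e-12) {
    stop_domain("rank of the input is below K; whitening is singular")
  }
  Z <- sqrt(n) * t(sv$v[, seq_len(K), drop = FALSE])   # K x n, unit row RMS
  M <- sv$u[, seq_len(K), drop = FALSE] %*% diag(sv$d[seq_len(K)] / sqrt(n), K, K)

  fit <- NULL; restarts_used <- 0L
  for (r in seq_len(max(1L, restarts))) {
    restarts_used <- r - 1L
    fit <- fastica_core(Z, K, seed + (r - 1L) * 1000003L, tol, max_iter)
    if (fit$converged) break
  }
  if (!fit$converged) {
    stop(structure(class = c("gwasdecomp_convergence_error", "error", "condition"),
                   list(message = sprintf(
                     "FastICA did not converge (%d restarts of %d iterations; last delta %.3g)",
                     restarts, max_iter, fit$delta), call = sys.call())))
  }
  W <- fit$W
  S <- W %*% Z                       # unit-RMS rows (W orthogonal)
  A <- M %*% t(W)
  ord <- order(colSums(A^2), decreasing = TRUE)
  S <- S[ord, , drop = FALSE]; A <- A[, ord, drop = FALSE]
  fx <- fix_signs(S, A)
  colnames(fx$S) <- colnames(V) %||% as_registry(X)$snp_id
  ve <- (sv$d^2 / sum(sv$d^2))[seq_len(K)]
  new_decomposition("ica", K, fx$S, fx$A,
                    rownames(V) %||% paste0("trait", seq_len(m)),
                    as_registry(X), sv$d, ve,
                    list(method = "ica", K = K, seed = seed, tol = tol,
                         max_iter = max_iter, iterations = fit$iter,
                         restarts_used = restarts_used, contrast = "logcosh",
                         centered = FALSE, variance_normalized = FALSE))
}

#' Cumulative variance explained at chosen dimensions
#'
#' @param d A `decomposition` (its full singular spectrum is used).
#' @param dims Integer vector of dimensions, each within the spectrum.
#' @return Data frame `(K, cumulative_variance)`.
#' @export
scree_table <- function(d, dims) {
  stopifnot(inherits(d, "decomposition"))
  spec <- d$singular_spectrum
  dims <- as.integer(dims)
  if (any(dims < 1L) || any(dims > length(spec))) {
    stop_domain("requested dimension exceeds the singular spectrum (length ",
                length(spec), ")")
  }
  cumfrac <- cumsum(spec^2) / sum(spec^2)
  data.frame(K = dims, cumulative_variance = cumfrac[dims])
}

# Square linear-assignment (minimum cost) by the shortest-augmenting-path
# (Jonker-Volgenant style) algorithm, O(n^3). Returns the assigned column
# for each row.
lsap_min <- function(a) {
  n <- nrow(a)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 0L
    minv <- rep(Inf, n + 1); used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- a[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0L) ans[p[j + 1]] <- j
  ans
}

#' Match components across two decompositions
#'
#' One-to-one assignment of components maximising the total absolute
#' Pearson correlation between paired SNP-loading rows (optimal linear
#' assignment; rectangular cases are padded, leaving the surplus
#' components unmatched).
#'
#' @param a,b `decomposition` objects sharing the same SNP registry.
#' @return Data frame `(index_a, index_b, sign, r)` for the
#'   `min(K_a, K_b)` matched pairs, ordered by `index_a`.
#' @export
align_components <- function(a, b) {
  stopifnot(inherits(a, "decomposition"), inherits(b, "decomposition"))
  if (!identical(colnames(a$snp_loadings), colnames(b$snp_loadings))) {
    stop_domain("decompositions do not share a SNP registry")
  }
  R <- suppressWarnings(stats::cor(t(a$snp_loadings), t(b$snp_loadings)))
  if (any(!is.finite(R))) stop_domain("constant loading row: correlation undefined")
  Ka <- nrow(R); Kb <- ncol(R); n <- max(Ka, Kb)
  cost <- matrix(0, n, n)
  cost[seq_len(Ka), seq_len(Kb)] <- -abs(R)
  asg <- lsap_min(cost)
  ia <- seq_len(Ka)[asg[seq_len(Ka)] <= Kb]
  ib <- asg[ia]
  r <- R[cbind(ia, ib)]
  out <- data.frame(index_a = ia, index_b = ib,
                    sign = ifelse(r >= 0, 1, -1), r = r)
  out[order(out$index_a), , drop = FALSE]
}

#' Write decomposition outputs to TSV and JSON files
#'
#' Emits `<prefix>_snp_loadings.tsv` (snp_id, chrom, pos, one column per
#' component), `<prefix>_trait_loadings.tsv`, `<prefix>_spectrum.tsv`
#' (singular values and cumulative variance) and `<prefix>_meta.json`
#' (the configuration fingerprint).
#'
#' @param d A `decomposition`.
#' @param prefix Output path prefix.
#' @return Character vector of file paths written, invisibly.
#' @export
write_decomposition <- function(d, prefix) {
  stopifnot(inherits(d, "decomposition"))
  comp <- rownames(d$snp_loadings)
  sl <- data.frame(snp_id = colnames(d$snp_loadings),
                   chrom = d$snp_registry$chrom,
                   pos = d$snp_registry$pos,
                   stringsAsFactors = FALSE)
  for (k in seq_len(d$K)) sl[[comp[k]]] <- format_full(d$snp_loadings[k, ])
  f1 <- paste0(prefix, "_snp_loadings.tsv")
  utils::write.table(sl, f1, sep = "\t", quote = FALSE, row.names = FALSE)

  tl <- data.frame(trait_id = d$trait_ids, stringsAsFactors = FALSE)
  for (k in seq_len(d$K)) tl[[comp[k]]] <- format_full(d$trait_loadings[, k])
  f2 <- paste0(prefix, "_trait_loadings.tsv")
  utils::write.table(tl, f2, sep = "\t", quote = FALSE, row.names = FALSE)

  spec <- data.frame(component = seq_along(d$singular_spectrum),
                     singular_value = format_full(d$singular_spectrum),
                     cumulative_variance = format_full(
                       cumsum(d$singular_spectrum^2) / sum(d$singular_spectrum^2)))
  f3 <- paste0(prefix, "_spectrum.tsv")
  utils::write.table(spec, f3, sep = "\t", quote = FALSE, row.names = FALSE)

  f4 <- paste0(prefix, "_meta.json")
  jsonlite::write_json(d$config, f4, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(f1, f2, f3, f4))
}
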