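# Inter-sample reproducibility of genomic components: global SNP-loading
# correlations, sparse-tail Fisher overlap, and the univariate GWAS
# benchmark.

#' Pairwise SNP-loading correlations between two decompositions
#'
#' Pearson correlation of every SNP-loading row of sample A with every row
#' of sample B, with two-sided p-values from the exact t-transform and
#' Bonferroni adjustment by the number of unique comparisons
#' (`K_a * K_b`).
#'
#' @param a,b `decomposition` objects sharing a SNP registry.
#' @return List with `corr` (K_a x K_b), `pvals` and `pvals_adj`.
#' @export
component_correlations <- function(a, b) {
  stopifnot(inherits(a, "decomposition"), inherits(b, "decomposition"))
  if (!identical(colnames(a$snp_loadings), colnames(b$snp_loadings))) {
    stop_domain("decompositions do not share a SNP registry")
  }
  sda <- apply(a$snp_loadings, 1, stats::sd)
  sdb <- apply(b$snp_loadings, 1, stats::sd)
  if (any(sda == 0) || any(sdb == 0)) {
    stop_domain("constant loading row(s): a#", paste(which(sda == 0), collapse = ","),
                " b#", paste(which(sdb == 0), collapse = ","),
                " have undefined correlations")
  }
  n <- ncol(a$snp_loadings)
  if (n < 3L) stop_domain("need at least 3 SNPs for a correlation p-value")
  R <- stats::cor(t(a$snp_loadings), t(b$snp_loadings))
  tstat <- R * sqrt((n - 2) / pmax(1 - R^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(R) >= 1] <- 0
  bonf <- nrow(R) * ncol(R)
  list(corr = R, pvals = p, pvals_adj = pmin(1, p * bonf), bonferroni = bonf)
}

#' Binarize standardized component loadings at a threshold
#'
#' Each SNP-loading row is standardized ((x - mean) / sd) and thresholded:
#' an entry is `TRUE` when the standardized loading exceeds `threshold`
#' (one-sided, the conventional reading of z-scaled component maps), or
#' when its absolute value does in `absolute` mode.
#'
#' @param d A `decomposition`.
#' @param threshold Standardized-loading cutoff (default 1).
#' @param absolute Threshold `|z|` instead of `z`.
#' @return Logical K x n matrix.
#' @export
binarize_loadings <- function(d, threshold = 1, absolute = FALSE) {
  stopifnot(inherits(d, "decomposition"))
  S <- d$snp_loadings
  Z <- t(scale(t(S)))
  if (any(!is.finite(Z))) stop_domain("constant loading row cannot be standardized")
  out <- if (absolute) abs(Z) > threshold else Z > threshold
  dimnames(out) <- dimnames(S)
  out
}

# Two-sided Fisher exact p for a 2x2 table by direct hypergeometric
# enumeration: sum of P(X = k) over the support where the point
# probability does not exceed the observed one (standard two-sided rule).
fisher_p_two_sided <- function(a, b, c, d) {
  m1 <- a + b; k <- a + c; N <- a + b + c + d
  support <- max(0L, m1 + k - N):min(m1, k)
  probs <- stats::dhyper(support, m1, N - m1, k)
  p_obs <- stats::dhyper(a, m1, N - m1, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Fisher exact test of overlap between two binarized loading rows
#'
#' Builds the 2x2 contingency table {both, a-only, b-only, neither} and
#' computes the two-sided Fisher exact p by hypergeometric enumeration.
#' Valid as an exact test when the SNPs are (approximately) independent,
#' i.e. after clumping at r-squared < 0.1.
#'
#' @param bin_a,bin_b Logical vectors of equal length (one component each).
#' @param n_tables Bonferroni factor: number of contingency tables in the
#'   family of comparisons (`K_a * K_b`); default 1.
#' @return List with `table` (2x2), `odds_ratio` (sample odds ratio;
#'   `Inf` sentinel when a margin is degenerate in favour of overlap),
#'   `p` and `p_adj`.
#' @export
overlap_fisher <- function(bin_a, bin_b, n_tables = 1) {
  if (length(bin_a) != length(bin_b)) stop_domain("rows must have equal length")
  n <- length(bin_a)
  if (n == 0L) stop_domain("empty loading rows")
  a <- sum(bin_a & bin_b); b <- sum(bin_a & !bin_b)
  c <- sum(!bin_a & bin_b); d <- sum(!bin_a & !bin_b)
  tab <- matrix(c(a, c, b, d), 2, 2,
                dimnames = list(a = c("TRUE", "FALSE"), b = c("TRUE", "FALSE")))
  orat <- if (b * c == 0) { if (a * d == 0) NaN else Inf } else (a * d) / (b * c)
  p <- fisher_p_two_sided(a, b, c, d)
  list(table = tab, odds_ratio = orat, p = p, p_adj = min(1, p * n_tables))
}

#' Per-trait univariate GWAS reproducibility
#'
#' Pearson correlation, across SNPs, of each trait's effect sizes in two
#' independent samples — the benchmark the component reproducibility is
#' judged against.
#'
#' @param Xa,Xb [effect_matrix()] objects with identical trait and SNP
#'   registries (same mode).
#' @return Named numeric vector of per-trait r with attribute `summary`
#'   (list `max`, `mean`, `sd`).
#' @export
univariate_reproducibility <- function(Xa, Xb) {
  stopifnot(inherits(Xa, "effect_matrix"), inherits(Xb, "effect_matrix"))
  if (!identical(Xa$trait_ids, Xb$trait_ids) ||
      !identical(Xa$snp_registry$snp_id, Xb$snp_registry$snp_id)) {
    stop_domain("effect matrices do not share trait/SNP registries")
  }
  r <- vapply(seq_len(nrow(Xa$values)), function(t) {
    stats::cor(Xa$values[t, ], Xb$values[t, ])
  }, numeric(1))
  names(r) <- Xa$trait_ids
  attr(r, "summary") <- list(max = max(r), mean = mean(r), sd = stats::sd(r))
  r
}

#' Full cross-sample reproducibility report
#'
#' Assembles the component-correlation matrix, the optimal component
#' matching, Fisher overlap tests of the binarized loading tails for every
#' component pair, the univariate GWAS benchmark, and the per-component
#' indicator of whether the matched |r| exceeds the mean univariate r —
#' the headline comparison for genomic components.
#'
#' @param a,b `decomposition` objects (discovery, replication).
#' @param Xa,Xb Matching [effect_matrix()] pair for the univariate
#'   benchmark.
#' @param threshold,absolute Passed to [binarize_loadings()].
#' @return A `repro_report` list: `corr_matrix`, `pvals_adj`,
#'   `matched_pairs` (with `abs_r` and `exceeds_univariate_mean`),
#'   `fisher_results`, `univariate_r`, `summary`.
#' @export
benchmark_report <- function(a, b, Xa, Xb, threshold = 1, absolute = FALSE) {
  cc <- component_correlations(a, b)
  pairs <- align_components(a, b)
  uni <- univariate_reproducibility(Xa, Xb)
  us <- attr(uni, "summary")

  bin_a <- binarize_loadings(a, threshold, absolute)
  bin_b <- binarize_loadings(b, threshold, absolute)
  n_tables <- a$K * b$K
  fisher <- vector("list", a$K * b$K)
  idx <- 1L
  for (i in seq_len(a$K)) {
    for (j in seq_len(b$K)) {
      ft <- overlap_fisher(bin_a[i, ], bin_b[j, ], n_tables)
      fisher[[idx]] <- data.frame(index_a = i, index_b = j,
                                  both = ft$table[1, 1], a_only = ft$table[1, 2],
                                  b_only = ft$table[2, 1], neither = ft$table[2, 2],
                                  odds_ratio = ft$odds_ratio,
                                  p = ft$p, p_adj = ft$p_adj)
      idx <- idx + 1L
    }
  }
  fisher <- do.call(rbind, fisher)

  pairs$abs_r <- abs(pairs$r)
  pairs$exceeds_univariate_mean <- pairs$abs_r > us$mean
  structure(list(corr_matrix = cc$corr,
                 pvals_adj = cc$pvals_adj,
                 matched_pairs = pairs,
                 fisher_results = fisher,
                 univariate_r = uni,
                 summary = list(comp_r_max = max(pairs$abs_r),
                                comp_r_mean = mean(pairs$abs_r),
                                uni_r_max = us$max,
                                uni_r_mean = us$mean,
                                uni_r_sd = us$sd)),
            class = "repro_report")
}

#' @export
print.repro_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "Cross-sample reproducibility report\n",
    "  matched components: %d; mean |r| = %.3f (max %.3f)\n",
    "  univariate benchmark: mean r = %.3f (max %.3f, sd %.3f)\n",
    "  components exceeding univariate mean: %d / %d\n"),
    nrow(x$matched_pairs), s$comp_r_mean, s$comp_r_max,
    s$uni_r_mean, s$uni_r_max, s$uni_r_sd,
    sum(x$matched_pairs$exceeds_univariate_mean), nrow(x$matched_pairs)))
  invisible(x)
}

#' Correlate trait loadings with univariate reproducibility
#'
#' Post-hoc check that a component is not driven by low-reproducibility
#' traits: Pearson correlation (with two-sided p) between a component's
#' trait loadings (absolute values by default) and the per-trait
#' univariate reproducibility vector.
#'
#' @param trait_loadings_column Numeric vector (one component's trait
#'   loadings).
#' @param univariate_r Per-trait reproducibility from
#'   [univariate_reproducibility()].
#' @param absolute Use `|loading|` (default) or the signed loadings.
#' @return List `(r, p)`.
#' @export
loading_vs_reproducibility <- function(trait_loadings_column, univariate_r,
                                       absolute = TRUE) {
  x <- if (absolute) abs(trait_loadings_column) else as.numeric(trait_loadings_column)
  y <- as.numeric(univariate_r)
  if (length(x) != length(y)) stop_domain("vectors must have equal length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_domain("constant vector: correlation undefined")
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value)
}
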