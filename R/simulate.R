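# Synthetic paired-GWAS generator: discovery/replication summary
# statistics sharing planted latent genomic factors, with block LD,
# MAF-dependent standard errors and modality-structured trait loadings.
# The generator is first-class code: it defines the study conditions
# under which the pipeline's recovery and reproducibility claims are
# tested.

#' Simulation configuration for a paired multi-trait GWAS
#'
#' Defaults emulate a desk-scale version of a paired brain-imaging GWAS
#' resource: two non-overlapping samples (discovery twice the size of
#' replication), a few latent genomic factors with sparse super-Gaussian
#' SNP loadings, trait loadings organised in modality blocks, block LD
#' laid out so default clumping keeps about one SNP per block, and
#' standard errors following the 1/sqrt(2 MAF (1-MAF) N) GWAS
#' approximation with an overall scale chosen so per-trait univariate
#' reproducibility sits in the ~0.1 regime typical of imaging GWAS.
#'
#' @param m_traits Number of traits.
#' @param n_snps Number of SNPs.
#' @param K_true Number of latent genomic factors (0 = pure noise).
#' @param sparsity Spike probability: chance a SNP loads on a factor.
#' @param factor_scale SD of non-zero (slab) factor loadings.
#' @param noise_sd Overall noise scale: the sampling SE of a MAF = 0.5
#'   SNP in the discovery sample.
#' @param modality_blocks Optional list with `n_blocks` (traits split into
#'   this many contiguous equal blocks) and `affinity` (n_blocks x K_true
#'   mean-loading matrix). Default: one block per factor; block g loads
#'   factor g at weight 1 with a 0.15 cross-block affinity floor, so every
#'   trait carries some of every factor (pervasive pleiotropy) while the
#'   mixing matrix stays full rank — K distinct blocks are required for K
#'   factors to be linearly identifiable in trait space.
#' @param maf_range Uniform MAF sampling range.
#' @param n_sample_a,n_sample_b Discovery/replication GWAS sample sizes
#'   (drive the SE ratio between samples).
#' @param ld_block_size SNPs per LD block.
#' @param within_block_r2 r-squared between SNPs of the same block
#'   (between blocks: 0).
#' @param seed Structure seed (latent factors, loadings, MAF, layout).
#' @param noise_seed Noise seed (sampling error of both samples); the
#'   two-seed split keeps the truth identical while noise varies.
#' @return A `sim_config` list.
#' @export
sim_config <- function(m_traits = 100L, n_snps = 2000L, K_true = 5L,
                       sparsity = 0.02, factor_scale = 1, noise_sd = 1.0,
                       modality_blocks = NULL,
                       maf_range = c(0.05, 0.5),
                       n_sample_a = 22000L, n_sample_b = 11000L,
                       ld_block_size = 10L, within_block_r2 = 0.8,
                       seed = 1L, noise_seed = NULL) {
  if (!(sparsity > 0 && sparsity < 1)) stop_domain("sparsity must be in (0,1)")
  if (noise_sd < 0) stop_domain("noise_sd must be >= 0")
  if (n_sample_a <= 1 || n_sample_b <= 1) stop_domain("sample sizes must exceed 1")
  if (K_true < 0) stop_domain("K_true must be >= 0")
  if (m_traits < 2 || n_snps < 2) stop_domain("need at least 2 traits and 2 SNPs")
  if (ld_block_size < 1 || ld_block_size > n_snps) stop_domain("invalid ld_block_size")
  if (!(within_block_r2 >= 0 && within_block_r2 < 1)) {
    stop_domain("within_block_r2 must be in [0,1)")
  }
  if (!(maf_range[1] > 0 && maf_range[2] <= 0.5 && maf_range[1] <= maf_range[2])) {
    stop_domain("maf_range must satisfy 0 < low <= high <= 0.5")
  }
  if (is.null(modality_blocks) && K_true > 0) {
    n_blocks <- min(as.integer(m_traits), as.integer(K_true))
    affinity <- matrix(0.15, n_blocks, K_true)
    for (k in seq_len(K_true)) affinity[(k - 1L) %% n_blocks + 1L, k] <- 1
    modality_blocks <- list(n_blocks = n_blocks, affinity = affinity)
  }
  if (K_true > 0 &&
      (nrow(modality_blocks$affinity) < 1 ||
       ncol(modality_blocks$affinity) != K_true)) {
    stop_domain("modality_blocks$affinity must be n_blocks x K_true")
  }
  structure(list(m_traits = as.integer(m_traits), n_snps = as.integer(n_snps),
                 K_true = as.integer(K_true), sparsity = sparsity,
                 factor_scale = factor_scale, noise_sd = noise_sd,
                 modality_blocks = modality_blocks, maf_range = maf_range,
                 n_sample_a = as.integer(n_sample_a),
                 n_sample_b = as.integer(n_sample_b),
                 ld_block_size = as.integer(ld_block_size),
                 within_block_r2 = within_block_r2,
                 seed = as.integer(seed),
                 noise_seed = as.integer(noise_seed %||% (seed + 1000003L))),
            class = "sim_config")
}

# SE of the per-allele effect for SNP j in a sample of size N:
# the standard GWAS approximation 1/sqrt(2 maf (1-maf) N) with the
# overall phenotype-variance scale kappa set so that a maf = 0.5 SNP in
# the discovery sample has SE exactly noise_sd.
sim_se <- function(maf, n_sample, cfg) {
  kappa <- cfg$noise_sd * sqrt(0.5 * cfg$n_sample_a)
  kappa / sqrt(2 * maf * (1 - maf) * n_sample)
}

# Genomic layout: LD blocks of consecutive SNPs, blocks spaced > 2 Mb so
# the default 1 Mb clumping window never spans blocks; blocks rotate over
# 22 autosome labels. Within-block spacing 1 kb.
sim_layout <- function(n_snps, block_size) {
  block <- (seq_len(n_snps) - 1L) %/% block_size + 1L
  within <- (seq_len(n_snps) - 1L) %% block_size
  chrom <- as.character((block - 1L) %% 22L + 1L)
  chrom_block <- (block - 1L) %/% 22L
  pos <- chrom_block * 2500000L + within * 1000L + 1L
  data.frame(snp_id = sprintf("rs%06d", seq_len(n_snps)), chrom = chrom,
             pos = pos, block = block, stringsAsFactors = FALSE)
}

#' Simulate a paired discovery/replication multi-trait GWAS
#'
#' Draws latent factor structure under the structure seed: spike-and-slab
#' SNP loadings (zero with probability `1 - sparsity`, else
#' `N(0, factor_scale^2)`), modality-block trait loadings
#' (`N(w_gk, 0.1 |w_gk| + 0.01)`), uniform MAFs and a block-LD layout.
#' Direct SNP loadings are convolved with the block LD (off-diagonal
#' r = sqrt(within_block_r2)) to give the marginal loadings a GWAS
#' measures; the true effect matrix is `A_true %*% S_true`. Under the
#' noise seed, each sample's betas are the truth plus independent
#' Gaussian error with the MAF- and sample-size-dependent SE; z = beta/se
#' and two-sided normal p-values follow.
#'
#' @param cfg A [sim_config()].
#' @return List with `tables_a`, `tables_b` (lists of [summary_stats()]),
#'   and `truth` (a `synthetic_truth`: `S_true` marginal loadings,
#'   `S_direct`, `A_true`, `registry` incl. LD blocks, `causal_blocks`,
#'   `maf`, `se_a`, `se_b`, `X_star`, `modality`).
#' @export
simulate_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  m <- cfg$m_traits; n <- cfg$n_snps; K <- cfg$K_true

  set.seed(cfg$seed)
  layout <- sim_layout(n, cfg$ld_block_size)
  maf <- stats::runif(n, cfg$maf_range[1], cfg$maf_range[2])

  if (K > 0) {
    S_direct <- matrix(stats::rnorm(K * n, 0, cfg$factor_scale) *
                         (stats::runif(K * n) < cfg$sparsity), K, n)
    r_off <- sqrt(cfg$within_block_r2)
    S_true <- S_direct
    if (r_off > 0 && cfg$ld_block_size > 1L) {
      for (b in unique(layout$block)) {
        idx <- which(layout$block == b)
        if (length(idx) > 1L) {
          Rb <- matrix(r_off, length(idx), length(idx)); diag(Rb) <- 1
          S_true[, idx] <- S_direct[, idx, drop = FALSE] %*% Rb
        }
      }
    }
    blocks <- cfg$modality_blocks
    g <- ((seq_len(m) - 1L) * blocks$n_blocks) %/% m + 1L
    W <- blocks$affinity[g, , drop = FALSE]
    A_true <- matrix(stats::rnorm(m * K, as.vector(W),
                                  0.1 * abs(as.vector(W)) + 0.01), m, K)
    X_star <- A_true %*% S_true
    causal_blocks <- sort(unique(layout$block[colSums(S_direct != 0) > 0]))
  } else {
    S_direct <- S_true <- matrix(0, 0, n)
    A_true <- matrix(0, m, 0)
    X_star <- matrix(0, m, n)
    g <- rep(1L, m)
    causal_blocks <- integer(0)
  }

  se_a <- sim_se(maf, cfg$n_sample_a, cfg)
  se_b <- sim_se(maf, cfg$n_sample_b, cfg)

  set.seed(cfg$noise_seed)
  E_a <- matrix(stats::rnorm(m * n), m, n) * rep(se_a, each = m)
  E_b <- matrix(stats::rnorm(m * n), m, n) * rep(se_b, each = m)
  beta_a <- X_star + E_a
  beta_b <- X_star + E_b

  alleles <- cbind(eff = rep(c("A", "C", "G", "T"), length.out = n),
                   oth = rep(c("G", "T", "A", "C"), length.out = n))
  trait_ids <- sprintf("trait%03d", seq_len(m))
  make_tables <- function(beta, se) {
    # floor keeps the noiseless (se -> 0) limit representable while
    # honouring the se > 0 table invariant
    se <- pmax(se, .Machine$double.xmin)
    lapply(seq_len(m), function(t) {
      z <- beta[t, ] / se
      summary_stats(trait_ids[t], data.frame(
        snp_id = layout$snp_id, chrom = layout$chrom, pos = layout$pos,
        effect_allele = alleles[, "eff"], other_allele = alleles[, "oth"],
        beta = beta[t, ], se = se,
        pval = pmax(2 * stats::pnorm(-abs(z)), 1e-300),
        stringsAsFactors = FALSE))
    })
  }

  truth <- structure(list(S_true = S_true, S_direct = S_direct,
                          A_true = A_true, X_star = X_star,
                          registry = layout, causal_blocks = causal_blocks,
                          maf = maf, se_a = se_a, se_b = se_b,
                          modality = g, cfg = cfg),
                     class = "synthetic_truth")
  list(tables_a = make_tables(beta_a, se_a),
       tables_b = make_tables(beta_b, se_b),
       truth = truth)
}

#' Block-LD source matching a simulated data set
#'
#' Builds the `ld_source` implied by the simulation's LD layout:
#' r-squared equal to `within_block_r2` inside each block, 0 between
#' blocks (sparse block-diagonal storage).
#'
#' @param truth A `synthetic_truth` from [simulate_pair()].
#' @return An `ld_source` with complete coverage.
#' @export
sim_ld_source <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  layout <- truth$registry
  r2 <- truth$cfg$within_block_r2
  mats <- lapply(split(seq_len(nrow(layout)), layout$block), function(idx) {
    B <- matrix(r2, length(idx), length(idx)); diag(B) <- 1
    B
  })
  sm <- Matrix::bdiag(mats)
  dimnames(sm) <- list(layout$snp_id, layout$snp_id)
  new_ld_source("matrix", sm, layout$snp_id)
}

#' Score recovery of planted factors by an estimated decomposition
#'
#' Optimal one-to-one assignment of estimated components to true factors
#' maximising total |Pearson r| of SNP loadings (over the SNPs shared by
#' the decomposition and the truth).
#'
#' @param estimated A `decomposition`.
#' @param truth A `synthetic_truth`.
#' @return List with `pairs` (data frame `factor`, `component`, `r`,
#'   `abs_r`), `per_factor_abs_r`, `mean_abs_r`, `K_mismatch`.
#' @export
recovery_score <- function(estimated, truth) {
  stopifnot(inherits(estimated, "decomposition"),
            inherits(truth, "synthetic_truth"))
  if (nrow(truth$S_true) == 0L) stop_domain("truth has no factors to recover")
  snps <- colnames(estimated$snp_loadings)
  idx <- match(snps, truth$registry$snp_id)
  if (anyNA(idx)) stop_domain("decomposition SNPs absent from the simulation registry")
  S_est <- estimated$snp_loadings
  S_tru <- truth$S_true[, idx, drop = FALSE]
  R <- suppressWarnings(stats::cor(t(S_tru), t(S_est)))
  R[!is.finite(R)] <- 0
  Kt <- nrow(R); Ke <- ncol(R); nsq <- max(Kt, Ke)
  cost <- matrix(0, nsq, nsq)
  cost[seq_len(Kt), seq_len(Ke)] <- -abs(R)
  asg <- lsap_min(cost)
  keep <- seq_len(Kt)[asg[seq_len(Kt)] <= Ke]
  pairs <- data.frame(factor = keep, component = asg[keep],
                      r = R[cbind(keep, asg[keep])])
  pairs$abs_r <- abs(pairs$r)
  list(pairs = pairs,
       per_factor_abs_r = stats::setNames(pairs$abs_r, paste0("factor", pairs$factor)),
       mean_abs_r = mean(pairs$abs_r),
       K_mismatch = Kt != Ke)
}
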