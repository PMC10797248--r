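# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# A small, fully explicit summary-statistics data frame.
toy_stats_df <- function(n = 3L, chrom = "1", beta = NULL, se = NULL,
                         pval = NULL, pos = NULL) {
  data.frame(
    snp_id = sprintf("rs%03d", seq_len(n)),
    chrom = chrom,
    pos = pos %||% (seq_len(n) * 1000L),
    effect_allele = rep(c("A", "C"), length.out = n),
    other_allele = rep(c("G", "T"), length.out = n),
    beta = beta %||% seq(0.1, by = 0.1, length.out = n),
    se = se %||% rep(0.05, n),
    pval = pval %||% rep(0.5, n),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random summary_stats tables for k traits over a shared SNP registry.
random_tables <- function(k = 3L, n = 20L, seed = 1L) {
  set.seed(seed)
  base <- toy_stats_df(n)
  lapply(seq_len(k), function(t) {
    df <- base
    df$beta <- rnorm(n, 0, 0.2)
    df$se <- runif(n, 0.01, 0.1)
    df$pval <- runif(n)
    summary_stats(sprintf("trait%02d", t), df)
  })
}

# Block-diagonal r^2 matrix over n SNPs: blocks of `size` at r2 `within`.
block_r2_matrix <- function(n, size, within, ids = sprintf("rs%03d", seq_len(n))) {
  m <- matrix(0, n, n)
  for (s in seq(1L, n, by = size)) {
    idx <- s:min(s + size - 1L, n)
    m[idx, idx] <- within
  }
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  m
}

# Independent brute-force transcription of the greedy windowed pruning
# rule, used as oracle: scan in (chrom, pos) order, keep a SNP iff r2 with
# every kept SNP on the same chromosome within the window is < r2_max.
oracle_prune <- function(info, r2mat, r2_max, window_bp) {
  o <- order(gwasdecomp:::chrom_rank(info$chrom), info$pos)
  id <- info$snp_id[o]; ch <- info$chrom[o]; ps <- info$pos[o]
  kept <- integer(0)
  for (i in seq_along(id)) {
    ok <- TRUE
    for (k in kept) {
      if (ch[k] == ch[i] && abs(ps[k] - ps[i]) <= window_bp &&
          r2mat[id[k], id[i]] >= r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  id[kept]
}

# Independent brute-force transcription of the clumping rule: iterate the
# p-sorted candidate list; each unclaimed candidate becomes a lead and
# claims unclaimed same-chromosome SNPs within the window at r2 > thresh.
oracle_clump <- function(pm, r2mat, window_bp, lead_p_max, clump_r2_max) {
  o <- order(pm$p_min, gwasdecomp:::chrom_rank(pm$chrom), pm$pos)
  id <- pm$snp_id; ch <- pm$chrom; ps <- pm$pos
  claimed <- setNames(rep(FALSE, nrow(pm)), id)
  leads <- character(0)
  members <- list()
  for (i in o) {
    if (pm$p_min[i] >= lead_p_max) next
    if (claimed[id[i]]) next
    claimed[id[i]] <- TRUE
    leads <- c(leads, id[i])
    for (j in seq_along(id)) {
      if (claimed[id[j]]) next
      if (ch[j] == ch[i] && abs(ps[j] - ps[i]) <= window_bp &&
          r2mat[id[i], id[j]] > clump_r2_max) {
        claimed[id[j]] <- TRUE
        members[[id[j]]] <- id[i]
      }
    }
  }
  list(leads = leads, members = members)
}

# Log-scale two-sided Fisher p by explicit enumeration with choose();
# independent of dhyper.
oracle_fisher_p <- function(a, b, c, d) {
  m1 <- a + b; k <- a + c; N <- a + b + c + d
  lp <- function(x) {
    lchoose(m1, x) + lchoose(N - m1, k - x) - lchoose(N, k)
  }
  support <- max(0L, m1 + k - N):min(m1, k)
  lps <- vapply(support, lp, numeric(1))
  obs <- lp(a)
  sum(exp(lps[lps <= obs + log(1 + 1e-7)]))
}

# Effect matrix with i.i.d. Gaussian entries and a usable registry.
random_effect_matrix <- function(m = 10L, n = 50L, seed = 1L, mode = "raw_beta") {
  set.seed(seed)
  reg <- data.frame(snp_id = sprintf("rs%04d", seq_len(n)),
                    chrom = as.character((seq_len(n) - 1L) %% 22L + 1L),
                    pos = seq_len(n) * 1000L,
                    effect_allele = "A", other_allele = "G",
                    stringsAsFactors = FALSE)
  effect_matrix(matrix(rnorm(m * n), m, n),
                sprintf("trait%03d", seq_len(m)), reg, mode)
}
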