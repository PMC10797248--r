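# LD pruning, min-p clumping, augmentation and the effective-SNP count.

test_that("min_p_across_traits takes the per-SNP minimum", {
  tabs <- random_tables(k = 2L, n = 3L, seed = 1)
  pm <- min_p_across_traits(tabs)
  expect_equal(pm$p_min, pmin(tabs[[1]]$pval, tabs[[2]]$pval))

  one <- min_p_across_traits(tabs[1])
  expect_equal(one$p_min, tabs[[1]]$pval)

  df <- toy_stats_df(2, pval = c(1, 1))
  t3 <- lapply(1:3, function(i) summary_stats(paste0("t", i), df))
  expect_equal(min_p_across_traits(t3)$p_min, c(1, 1))
})

test_that("ld_prune keeps the first of a correlated pair and all independent SNPs", {
  info <- data.frame(snp_id = c("rs001", "rs002"), chrom = "1",
                     pos = c(100L, 200L), stringsAsFactors = FALSE)
  m <- matrix(c(1, 0.9, 0.9, 1), 2, 2, dimnames = list(info$snp_id, info$snp_id))
  expect_equal(ld_prune(info, ld_from_matrix(m), r2_max = 0.3), "rs001")

  m0 <- diag(2); dimnames(m0) <- dimnames(m)
  expect_equal(ld_prune(info, ld_from_matrix(m0), r2_max = 0.3),
               c("rs001", "rs002"))
})

test_that("ld_prune matches a brute-force transcription of the greedy rule", {
  set.seed(42)
  for (rep in 1:10) {
    n <- 50L
    ids <- sprintf("rs%03d", seq_len(n))
    info <- data.frame(snp_id = ids,
                       chrom = as.character(sample(1:2, n, replace = TRUE)),
                       pos = sample.int(5000L, n),
                       stringsAsFactors = FALSE)
    # random block LD plus noise, symmetrised
    m <- block_r2_matrix(n, size = 5L, within = runif(1, 0.2, 0.9), ids = ids)
    noise <- matrix(runif(n * n, 0, 0.15), n, n)
    m <- pmin(pmax((m + (noise + t(noise)) / 2), 0), 1); diag(m) <- 1
    ld <- ld_from_matrix(m)
    r2max <- runif(1, 0.2, 0.6); win <- sample(c(500L, 1500L, 5000L), 1)
    expect_equal(ld_prune(info, ld, r2max, win),
                 oracle_prune(info, m, r2max, win))
  }
})

test_that("clump follows the lead/member rules on forced examples", {
  pm <- data.frame(snp_id = c("rs001", "rs002", "rs003"), chrom = "1",
                   pos = c(1000L, 2000L, 3000L),
                   p_min = c(1e-8, 1e-6, 0.5), stringsAsFactors = FALSE)
  m <- diag(3); m[1, 2] <- m[2, 1] <- 0.5
  dimnames(m) <- list(pm$snp_id, pm$snp_id)
  cl <- clump(pm, ld_from_matrix(m), clump_config())
  expect_equal(cl$leads$snp_id, "rs001")
  expect_equal(cl$members$snp_id, "rs002")
  expect_equal(cl$members$lead, "rs001")
  # rs003: p too large, never a lead, not claimed (r2 = 0)
  expect_false("rs003" %in% c(cl$leads$snp_id, cl$members$snp_id))

  # different chromosomes: window never spans, both leads
  pm2 <- data.frame(snp_id = c("rs001", "rs002"), chrom = c("1", "2"),
                    pos = c(1000L, 1000L), p_min = c(1e-8, 1e-7),
                    stringsAsFactors = FALSE)
  m2 <- matrix(c(1, 0.99, 0.99, 1), 2, 2, dimnames = list(pm2$snp_id, pm2$snp_id))
  cl2 <- clump(pm2, ld_from_matrix(m2), clump_config())
  expect_setequal(cl2$leads$snp_id, c("rs001", "rs002"))
})

test_that("clump matches a brute-force oracle and ignores input row order", {
  set.seed(99)
  for (rep in 1:10) {
    n <- 100L
    ids <- sprintf("rs%03d", seq_len(n))
    pm <- data.frame(snp_id = ids,
                     chrom = as.character(sample(1:3, n, replace = TRUE)),
                     pos = sample.int(3e6L, n),
                     p_min = 10^runif(n, -9, 0), stringsAsFactors = FALSE)
    m <- block_r2_matrix(n, size = 10L, within = runif(1, 0.15, 0.8), ids = ids)
    ld <- ld_from_matrix(m)
    cfg <- clump_config()
    cl <- clump(pm, ld, cfg)
    orc <- oracle_clump(pm, m, cfg$clump_window_bp, cfg$lead_p_max, cfg$clump_r2_max)
    expect_equal(cl$leads$snp_id, orc$leads)
    expect_equal(sort(cl$members$snp_id), sort(names(orc$members)))
    expect_equal(cl$members$lead[order(cl$members$snp_id)],
                 unlist(orc$members)[sort(names(orc$members))],
                 ignore_attr = TRUE)

    # row-order invariance
    shuf <- pm[sample.int(n), ]
    cl_shuf <- clump(shuf, ld, cfg)
    expect_equal(cl_shuf$leads$snp_id, cl$leads$snp_id)
  }
})

test_that("pruning then clumping at defaults keeps one lead per causal block", {
  # strongly powered scenario: small SE, sparse strong factors
  cfg <- sim_config(m_traits = 20L, n_snps = 300L, K_true = 3L,
                    sparsity = 0.05, noise_sd = 0.05,
                    ld_block_size = 10L, within_block_r2 = 0.5, seed = 31L)
  sim <- simulate_pair(cfg)
  ld <- sim_ld_source(sim$truth)
  pm <- min_p_across_traits(sim$tables_a)
  kept <- ld_prune(pm[c("snp_id", "chrom", "pos")], ld, r2_max = 0.3)
  cl <- clump(pm[pm$snp_id %in% kept, ], ld, clump_config())
  reg <- sim$truth$registry
  pmk <- pm[pm$snp_id %in% kept, ]
  block_min_p <- tapply(pmk$p_min, reg$block[match(pmk$snp_id, reg$snp_id)], min)
  detectable <- intersect(sim$truth$causal_blocks,
                          as.integer(names(block_min_p)[block_min_p < 1e-5]))
  blocks <- reg$block[match(cl$leads$snp_id, reg$snp_id)]
  expect_gt(length(detectable), 0)
  for (b in detectable) {
    expect_equal(sum(blocks == b), 1L)
  }
})

test_that("augment_lead_snps unions in order with dedup and addition count", {
  out <- augment_lead_snps(c("a", "b"), list(c("b", "c")))
  expect_equal(as.character(out), c("a", "b", "c"))
  expect_equal(attr(out, "n_added"), 1L)

  out2 <- augment_lead_snps(c("a", "b"), list(character(0)))
  expect_equal(as.character(out2), c("a", "b"))
  expect_equal(attr(out2, "n_added"), 0L)

  out3 <- augment_lead_snps(c("a"), list(c("d"), c("d", "e")))
  expect_equal(as.character(out3), c("a", "d", "e"))

  # registry completion requires coordinates
  reg <- data.frame(snp_id = "a", chrom = "1", pos = 1L,
                    stringsAsFactors = FALSE)
  expect_error(augment_lead_snps("a", list("x"), registry = reg), "coordinates")
  ext <- data.frame(snp_id = "x", chrom = "2", pos = 5L, stringsAsFactors = FALSE)
  out4 <- augment_lead_snps("a", list(ext), registry = reg)
  expect_equal(attr(out4, "registry")$snp_id, c("a", "x"))
})

test_that("effective_n_snps follows the eigenvalue formula and its bounds", {
  ids <- sprintf("rs%03d", 1:10)
  expect_equal(effective_n_snps(ld_from_matrix(diag(10), ids)), 10)

  m2 <- matrix(1, 2, 2, dimnames = list(ids[1:2], ids[1:2]))
  expect_equal(effective_n_snps(ld_from_matrix(m2)), 1)

  # exchangeable correlation r = 0.3 vs a direct eigen-solve oracle
  r <- 0.3
  C <- matrix(r, 5, 5); diag(C) <- 1
  ld <- ld_from_matrix(C^2, ids[1:5])  # store r2; sqrt recovers |r|
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(effective_n_snps(ld), 5 - sum(pmax(ev - 1, 0)), tolerance = 1e-8)

  # shrinkage: M_eff <= M, equality iff identity
  set.seed(8)
  G <- matrix(rnorm(200), 20, 10)
  ldg <- ld_from_genotypes(G, snp_ids = ids)
  expect_lt(effective_n_snps(ldg), 10)
})

test_that("long-table LD sources honour window semantics", {
  tab <- data.frame(SNP_A = "rs001", SNP_B = "rs002", R2 = 0.9)
  ids <- c("rs001", "rs002", "rs003")
  info <- data.frame(snp_id = ids, chrom = "1", pos = c(100L, 200L, 300L),
                     stringsAsFactors = FALSE)
  # declared window: the rs001-rs003 pair is within-window but absent -> strict error
  ld <- ld_from_table(tab, snp_ids = ids, window_bp = 1000L)
  expect_error(ld_prune(info, ld, r2_max = 0.3, window_bp = 1000L), "coverage")
  # lenient treats it as zero
  kept <- ld_prune(info, ld, r2_max = 0.3, window_bp = 1000L, strict = FALSE)
  expect_equal(kept, c("rs001", "rs003"))
  # a complete (no declared window) table works in strict mode
  ld2 <- ld_from_table(tab, snp_ids = ids)
  expect_equal(ld_prune(info, ld2, r2_max = 0.3, window_bp = 1000L),
               c("rs001", "rs003"))
})
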