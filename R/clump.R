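# LD pruning, min-p clumping across traits, lead-SNP augmentation and the
# effective-independent-SNP count.

#' Clumping configuration
#'
#' Defaults follow the standard brain-GWAS clumping recipe: a global prune
#' at r-squared < 0.3, then clumping of the per-SNP minimum p-value across
#' traits with a 1 Mb window, lead p-value threshold 1e-5 and member
#' threshold r-squared > 0.1.
#'
#' @param prune_r2_max Pruning ceiling; retained SNPs have pairwise
#'   r-squared below this within the window.
#' @param clump_window_bp Genomic window (bp) for both pruning and member
#'   assignment.
#' @param lead_p_max Only SNPs with min-p below this can become leads.
#' @param clump_r2_max Members are claimed at r-squared above this.
#' @return A `clump_config` list.
#' @export
clump_config <- function(prune_r2_max = 0.3, clump_window_bp = 1e6,
                         lead_p_max = 1e-5, clump_r2_max = 0.1) {
  if (!(prune_r2_max > 0 && prune_r2_max <= 1)) stop_domain("prune_r2_max must be in (0,1]")
  if (!(clump_r2_max > 0 && clump_r2_max < 1)) stop_domain("clump_r2_max must be in (0,1)")
  if (clump_window_bp <= 0) stop_domain("clump_window_bp must be positive")
  if (!(lead_p_max > 0 && lead_p_max <= 1)) stop_domain("lead_p_max must be in (0,1]")
  structure(list(prune_r2_max = prune_r2_max,
                 clump_window_bp = as.numeric(clump_window_bp),
                 lead_p_max = lead_p_max,
                 clump_r2_max = clump_r2_max),
            class = "clump_config")
}

#' Per-SNP minimum p-value across traits
#'
#' The clumping significance track: for every SNP, the smallest p-value it
#' attains across all trait GWASs.
#'
#' @param tables List of [summary_stats()] objects with identical SNP sets.
#' @return Data frame `(snp_id, chrom, pos, p_min)` in first-table order.
#' @export
min_p_across_traits <- function(tables) {
  if (length(tables) < 1L) stop_domain("need at least one table")
  first <- tables[[1L]]
  snps <- first$snp_id
  p_min <- first$pval
  for (tb in tables[-1L]) {
    idx <- match(snps, tb$snp_id)
    if (anyNA(idx) || nrow(tb) != length(snps)) {
      stop_domain("SNP sets are not harmonized across tables (trait '",
                  trait_id(tb), "')")
    }
    p_min <- pmin(p_min, tb$pval[idx])
  }
  data.frame(snp_id = snps, chrom = first$chrom, pos = first$pos,
             p_min = p_min, stringsAsFactors = FALSE)
}

#' Greedy windowed LD pruning
#'
#' Scans SNPs in genomic order (chromosome, position) and keeps a SNP iff
#' its r-squared with every previously kept SNP within `window_bp` on the
#' same chromosome is below `r2_max`. Deterministic.
#'
#' @param snp_info Data frame with `snp_id`, `chrom`, `pos`.
#' @param ld An `ld_source` covering the SNPs.
#' @param r2_max Pruning ceiling (default 0.3).
#' @param window_bp Window in bp (default 1 Mb).
#' @param strict Error on unknown within-window pairs (declared-window
#'   table sources); lenient treats them as 0.
#' @return Character vector of kept SNP ids, in genomic order.
#' @export
ld_prune <- function(snp_info, ld, r2_max = 0.3, window_bp = 1e6, strict = TRUE) {
  ord <- genomic_order(snp_info$chrom, snp_info$pos)
  info <- snp_info[ord, , drop = FALSE]
  n <- nrow(info)
  kept <- logical(n)
  for (i in seq_len(n)) {
    prev <- which(kept & info$chrom == info$chrom[i] &
                    abs(info$pos - info$pos[i]) <= window_bp)
    if (length(prev)) {
      r2 <- ld_query(ld, ld_index(ld, info$snp_id[prev]),
                     ld_index(ld, info$snp_id[i]))
      if (strict && any(!r2$known)) {
        bad <- info$snp_id[prev][!r2$known]
        stop_domain("LD coverage error at SNP '", info$snp_id[i], "': ",
                    paste(utils::head(bad, 5), collapse = ", "))
      }
      kept[i] <- all(r2$r2 < r2_max)
    } else {
      kept[i] <- TRUE
    }
  }
  info$snp_id[kept]
}

#' Min-p clumping into lead SNPs and members
#'
#' Candidates with `p_min < lead_p_max` are visited in ascending p (ties by
#' chromosome, then position). Each unclaimed candidate becomes a lead and
#' claims all still-unclaimed SNPs within `clump_window_bp` on the same
#' chromosome whose r-squared with the lead exceeds `clump_r2_max`.
#'
#' @param p_min Data frame from [min_p_across_traits()] (`snp_id`, `chrom`,
#'   `pos`, `p_min`).
#' @param ld An `ld_source`.
#' @param cfg A [clump_config()].
#' @param strict Error on unknown within-window LD pairs.
#' @return List with `leads` (data frame `snp_id`, `chrom`, `pos`, `p_min`
#'   in selection order) and `members` (data frame `snp_id`, `lead`).
#' @export
clump <- function(p_min, ld, cfg = clump_config(), strict = TRUE) {
  stopifnot(inherits(cfg, "clump_config"))
  info <- p_min[order(p_min$p_min, chrom_rank(p_min$chrom), p_min$pos), , drop = FALSE]
  n_all <- nrow(p_min)
  claimed <- stats::setNames(rep(FALSE, n_all), p_min$snp_id)
  lead_rows <- integer(0)
  member_snp <- character(0); member_lead <- character(0)
  cand <- which(info$p_min < cfg$lead_p_max)
  for (i in cand) {
    id <- info$snp_id[i]
    if (claimed[id]) next
    claimed[id] <- TRUE
    lead_rows <- c(lead_rows, i)
    near <- which(p_min$chrom == info$chrom[i] &
                    abs(p_min$pos - info$pos[i]) <= cfg$clump_window_bp &
                    !claimed[p_min$snp_id] & p_min$snp_id != id)
    if (length(near)) {
      q <- ld_query(ld, ld_index(ld, p_min$snp_id[near]), ld_index(ld, id))
      if (strict && any(!q$known)) {
        bad <- p_min$snp_id[near][!q$known]
        stop_domain("LD coverage error at lead '", id, "': ",
                    paste(utils::head(bad, 5), collapse = ", "))
      }
      take <- near[q$r2 > cfg$clump_r2_max]
      if (length(take)) {
        claimed[p_min$snp_id[take]] <- TRUE
        member_snp <- c(member_snp, p_min$snp_id[take])
        member_lead <- c(member_lead, rep(id, length(take)))
      }
    }
  }
  list(leads = info[lead_rows, c("snp_id", "chrom", "pos", "p_min")],
       members = data.frame(snp_id = member_snp, lead = member_lead,
                            stringsAsFactors = FALSE))
}

#' Augment clumped lead SNPs with external lead lists
#'
#' Set union preserving order: the original leads first, then novel
#' external SNPs in input order, duplicates removed. Intended for folding
#' in disease-GWAS lead variants (e.g. ADHD, Alzheimer's) so downstream
#' components stay sensitive to those loci.
#'
#' @param leads Character vector of lead SNP ids (or the `leads` data frame
#'   from [clump()]).
#' @param external List of external lead sets; each a character vector, or
#'   a data frame with `snp_id` (+ `chrom`, `pos` when registry completion
#'   is requested).
#' @param registry Optional registry data frame to extend with coordinates
#'   of novel SNPs; external entries lacking coordinates then error.
#' @return Character vector of SNP ids with attributes `n_added` and (when
#'   `registry` given) `registry`.
#' @export
augment_lead_snps <- function(leads, external, registry = NULL) {
  if (is.data.frame(leads)) leads <- leads$snp_id
  out <- as.character(leads)
  n_added <- 0L
  reg_new <- registry
  for (ext in external) {
    if (is.data.frame(ext)) {
      ids <- as.character(ext$snp_id)
    } else {
      ids <- as.character(ext)
      ext <- NULL
    }
    for (k in seq_along(ids)) {
      if (ids[k] %in% out) next
      out <- c(out, ids[k])
      n_added <- n_added + 1L
      if (!is.null(reg_new) && !(ids[k] %in% reg_new$snp_id)) {
        if (is.null(ext) || !all(c("chrom", "pos") %in% names(ext))) {
          stop_domain("external SNP '", ids[k],
                      "' lacks coordinates needed to complete the registry")
        }
        row <- ext[k, intersect(names(reg_new), names(ext)), drop = FALSE]
        pad <- setdiff(names(reg_new), names(row))
        for (p in pad) row[[p]] <- NA
        reg_new <- rbind(reg_new, row[names(reg_new)])
      }
    }
  }
  attr(out, "n_added") <- n_added
  if (!is.null(registry)) attr(out, "registry") <- reg_new
  out
}

#' Effective number of independent SNPs
#'
#' Eigenvalue-based effective-test count of the Li-Ji family: for the
#' eigenvalues \eqn{\lambda_i} of the SNP correlation matrix,
#' \eqn{M_{eff} = M - \sum_i (\lambda_i - 1)\,[\lambda_i > 1]}, computed
#' per LD block and summed. Equals M iff the correlation matrix is the
#' identity; 1 for a fully dependent pair.
#'
#' @param ld An `ld_source`. Signed correlations are used when available
#'   (genotype sources); otherwise the positive square root of r-squared.
#' @param snps SNP ids to evaluate (default: all SNPs of the source).
#' @param blocks Optional list of SNP-id vectors declaring block-diagonal
#'   structure; blocks are processed independently.
#' @return Effective SNP count (numeric scalar).
#' @export
effective_n_snps <- function(ld, snps = NULL, blocks = NULL) {
  snps <- snps %||% ld$snp_ids
  if (is.null(blocks)) blocks <- list(snps)
  total <- 0
  for (blk in blocks) {
    idx <- ld_index(ld, blk)
    C <- if (!is.null(ld$r_signed)) ld$r_signed[idx, idx, drop = FALSE]
         else sqrt(as.matrix(ld$r2[idx, idx, drop = FALSE]))
    M <- length(blk)
    if (M == 1L) { total <- total + 1; next }
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-6 * M) {
      stop_domain("correlation matrix is not positive semidefinite (min eigenvalue ",
                  format(min(ev)), ")")
    }
    total <- total + (M - sum(pmax(ev - 1, 0)))
  }
  total
}
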