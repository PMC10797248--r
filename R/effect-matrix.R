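# Stacking per-trait summary statistics into the traits-by-SNPs effect
# matrix (raw betas or z-values), with allele harmonization.

#' Construct an effect matrix
#'
#' Low-level constructor; most users build effect matrices with
#' [assemble_effect_matrix()].
#'
#' @param values m x n numeric matrix (traits by SNPs), no missing entries.
#' @param trait_ids Character vector, length m, unique.
#' @param snp_registry Data frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele` (and optionally `other_allele`), one row per column of
#'   `values`, `snp_id` unique.
#' @param mode `"raw_beta"` or `"z_value"`.
#' @return An `effect_matrix` object.
#' @export
effect_matrix <- function(values, trait_ids, snp_registry,
                          mode = c("raw_beta", "z_value")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop_domain("effect matrix has non-finite entries")
  if (length(trait_ids) != nrow(values)) stop_domain("trait_ids length != nrow(values)")
  if (nrow(snp_registry) != ncol(values)) stop_domain("snp_registry rows != ncol(values)")
  if (anyDuplicated(trait_ids)) stop_domain("trait_ids must be unique")
  if (anyDuplicated(snp_registry$snp_id)) stop_domain("snp_id must be unique in registry")
  dimnames(values) <- list(trait_ids, snp_registry$snp_id)
  structure(list(values = values,
                 trait_ids = as.character(trait_ids),
                 snp_registry = as.data.frame(snp_registry),
                 mode = mode),
            class = "effect_matrix")
}

#' @export
print.effect_matrix <- function(x, ...) {
  cat(sprintf("effect_matrix: %d traits x %d SNPs, mode = %s\n",
              nrow(x$values), ncol(x$values), x$mode))
  invisible(x)
}

#' @export
dim.effect_matrix <- function(x) dim(x$values)

#' @export
as.matrix.effect_matrix <- function(x, ...) x$values

# Orientation of a table's alleles against the registry at shared SNPs:
# +1 match, -1 swap, NA otherwise (strand-ambiguous mismatch).
allele_orientation <- function(eff, oth, ref_eff, ref_oth) {
  out <- rep(NA_real_, length(eff))
  out[eff == ref_eff & oth == ref_oth] <- 1
  out[eff == ref_oth & oth == ref_eff] <- -1
  out
}

#' Stack per-trait GWAS tables into a traits-by-SNPs effect matrix
#'
#' Builds the m x n matrix of per-allele effect sizes (or z-values) across
#' traits. The first table defines the reference effect allele per SNP;
#' tables whose effect/other alleles are swapped at a SNP contribute the
#' sign-flipped effect. A SNP at which alleles neither match nor swap is a
#' harmonization error.
#'
#' @param tables List of [summary_stats()] objects (at least two).
#' @param snp_subset Character vector of SNP ids defining the columns, in
#'   order. Default: SNPs common to all tables, in first-table order.
#' @param mode `"raw_beta"` for betas, `"z_value"` for beta/se.
#' @param missing `"strict"` errors when a subset SNP is absent from a
#'   table; `"lenient"` drops that column and records it in attribute
#'   `dropped_snps`.
#' @return An [effect_matrix()]; registry taken from the first table.
#' @export
assemble_effect_matrix <- function(tables, snp_subset = NULL,
                                   mode = c("raw_beta", "z_value"),
                                   missing = c("strict", "lenient")) {
  mode <- match.arg(mode)
  missing <- match.arg(missing)
  if (length(tables) < 2L) stop_domain("need at least two traits to assemble an effect matrix")
  ok <- vapply(tables, inherits, logical(1), "summary_stats")
  if (!all(ok)) stop_domain("all tables must be summary_stats objects")
  trait_ids <- vapply(tables, trait_id, character(1))
  if (anyDuplicated(trait_ids)) stop_domain("duplicate trait ids among tables")

  first <- tables[[1L]]
  if (is.null(snp_subset)) {
    snp_subset <- first$snp_id
    for (tb in tables[-1L]) snp_subset <- snp_subset[snp_subset %in% tb$snp_id]
    if (length(snp_subset) == 0L) stop_domain("no SNPs shared by all tables")
  } else {
    snp_subset <- as.character(snp_subset)
    if (anyDuplicated(snp_subset)) stop_domain("snp_subset contains duplicates")
  }

  dropped <- character(0)
  for (k in seq_along(tables)) {
    absent <- setdiff(snp_subset, tables[[k]]$snp_id)
    if (length(absent)) {
      if (missing == "strict") {
        stop_domain("SNP(s) missing from trait '", trait_ids[k], "': ",
                    paste(utils::head(absent, 10), collapse = ", "))
      }
      dropped <- union(dropped, absent)
    }
  }
  snp_subset <- setdiff(snp_subset, dropped)
  if (length(snp_subset) == 0L) stop_domain("no SNPs left after dropping missing columns")

  ridx <- match(snp_subset, first$snp_id)
  registry <- data.frame(snp_id = snp_subset,
                         chrom = first$chrom[ridx],
                         pos = first$pos[ridx],
                         effect_allele = first$effect_allele[ridx],
                         other_allele = first$other_allele[ridx],
                         stringsAsFactors = FALSE)

  m <- length(tables); n <- length(snp_subset)
  values <- matrix(NA_real_, m, n)
  for (k in seq_along(tables)) {
    tb <- tables[[k]]
    idx <- match(snp_subset, tb$snp_id)
    orient <- allele_orientation(tb$effect_allele[idx], tb$other_allele[idx],
                                 registry$effect_allele, registry$other_allele)
    if (anyNA(orient)) {
      bad <- snp_subset[is.na(orient)]
      stop_domain("strand-ambiguous allele mismatch in trait '", trait_ids[k],
                  "' at SNP(s): ", paste(utils::head(bad, 10), collapse = ", "))
    }
    v <- tb$beta[idx]
    if (mode == "z_value") v <- v / tb$se[idx]
    values[k, ] <- orient * v
  }

  em <- effect_matrix(values, trait_ids, registry, mode)
  attr(em, "dropped_snps") <- dropped
  em
}

#' Write an effect matrix to TSV plus a JSON sidecar
#'
#' The TSV holds one row per trait (first column `trait_id`, remaining
#' columns one per SNP); the sidecar JSON (`<path>.json`) stores the SNP
#' registry and the mode. Values are written at full precision so the
#' round trip is bit-identical.
#'
#' @param em An [effect_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_effect_matrix <- function(em, path) {
  stopifnot(inherits(em, "effect_matrix"))
  vals <- apply(em$values, 2, format_full)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
  out <- cbind(trait_id = em$trait_ids, vals)
  colnames(out) <- c("trait_id", em$snp_registry$snp_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(mode = em$mode, snp_registry = em$snp_registry),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an effect matrix written by [write_effect_matrix()]
#'
#' @param path TSV path (sidecar `<path>.json` must exist).
#' @return An [effect_matrix()].
#' @export
read_effect_matrix <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar)) {
    stop_format("effect matrix TSV or JSON sidecar not found at ", path)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character")
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  effect_matrix(values, tab$trait_id, as.data.frame(meta$snp_registry),
                mode = meta$mode)
}
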