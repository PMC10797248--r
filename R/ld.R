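# LD sources: providers of pairwise r^2 between SNPs. Three constructors
# (square matrix, long pair table, genotype dosages) feeding one query
# interface used by pruning, clumping and the effective-SNP count.

new_ld_source <- function(kind, r2, snp_ids, r_signed = NULL,
                          complete = TRUE, window_bp = NULL) {
  structure(list(kind = kind, r2 = r2, snp_ids = snp_ids,
                 r_signed = r_signed, complete = complete,
                 window_bp = window_bp),
            class = "ld_source")
}

#' @export
print.ld_source <- function(x, ...) {
  cat(sprintf("ld_source (%s): %d SNPs, %s pairwise coverage\n",
              x$kind, length(x$snp_ids),
              if (x$complete) "complete" else "declared-window"))
  invisible(x)
}

#' LD source from a square r-squared matrix
#'
#' @param m Square symmetric matrix of pairwise r-squared values in
#'   \eqn{[0,1]} with unit diagonal; SNP ids from `snp_ids` or
#'   `rownames(m)`.
#' @param snp_ids Optional SNP ids overriding the dimnames.
#' @return An `ld_source` with complete pairwise coverage.
#' @export
ld_from_matrix <- function(m, snp_ids = NULL) {
  snp_ids <- snp_ids %||% rownames(m)
  if (is.null(snp_ids)) stop_domain("r2 matrix needs SNP ids (rownames or snp_ids)")
  if (nrow(m) != ncol(m) || nrow(m) != length(snp_ids)) {
    stop_domain("r2 matrix must be square and match snp_ids")
  }
  mx <- as.matrix(m)
  if (max(abs(mx - t(mx))) > 1e-8) stop_domain("r2 matrix must be symmetric")
  if (min(mx) < -1e-8 || max(mx) > 1 + 1e-8) stop_domain("r2 values must lie in [0,1]")
  if (max(abs(diag(mx) - 1)) > 1e-8) stop_domain("r2 diagonal must be 1")
  dimnames(mx) <- list(snp_ids, snp_ids)
  new_ld_source("matrix", mx, snp_ids)
}

#' LD source from a long pairwise table
#'
#' Accepts three whitespace-delimited columns `SNP_A SNP_B R2` (the PLINK
#' `--ld-window` output dialect: extra columns such as CHR/BP are ignored,
#' matching on column names case-insensitively). Pairs absent from the
#' table count as r-squared 0 only when the two SNPs are on different
#' chromosomes or farther apart than `window_bp`; a missing within-window
#' pair is unknown and raises an LD-coverage error in strict queries.
#'
#' @param table Data frame or file path with columns `snp_a`, `snp_b`,
#'   `r2` (case-insensitive; `SNP_A/SNP_B/R2` accepted).
#' @param snp_ids Optional full SNP universe (defaults to ids seen in the
#'   table).
#' @param window_bp Declared window within which absent pairs are unknown
#'   rather than zero; `NULL` means the table is declared complete.
#' @return An `ld_source`.
#' @export
ld_from_table <- function(table, snp_ids = NULL, window_bp = NULL) {
  if (is.character(table) && length(table) == 1L) {
    table <- utils::read.table(table, header = TRUE, stringsAsFactors = FALSE)
  }
  nm <- tolower(names(table))
  need <- c("snp_a", "snp_b", "r2")
  if (!all(need %in% nm)) {
    stop_format("LD table needs columns SNP_A, SNP_B, R2 (got: ",
                paste(names(table), collapse = ", "), ")")
  }
  a <- as.character(table[[which(nm == "snp_a")[1]]])
  b <- as.character(table[[which(nm == "snp_b")[1]]])
  r2 <- as.numeric(table[[which(nm == "r2")[1]]])
  if (any(r2 < -1e-8 | r2 > 1 + 1e-8)) stop_domain("r2 values must lie in [0,1]")
  snp_ids <- snp_ids %||% unique(c(a, b))
  unknown <- setdiff(c(a, b), snp_ids)
  if (length(unknown)) {
    stop_domain("LD table names SNPs outside the registry: ",
                paste(utils::head(unknown, 5), collapse = ", "))
  }
  i <- match(a, snp_ids); j <- match(b, snp_ids)
  n <- length(snp_ids)
  sm <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(r2, r2),
                             dims = c(n, n), use.last.ij = TRUE)
  diag(sm) <- 1
  dimnames(sm) <- list(snp_ids, snp_ids)
  new_ld_source("table", sm, snp_ids,
                complete = is.null(window_bp), window_bp = window_bp)
}

#' LD source from a genotype dosage matrix
#'
#' r-squared is the squared Pearson correlation of dosages; the signed
#' correlation is retained for the effective-independent-SNP count.
#'
#' @param dosages Numeric matrix, individuals in rows, SNPs in columns
#'   (column names are the SNP ids).
#' @param snp_ids Optional ids overriding column names.
#' @return An `ld_source` with complete coverage and signed r.
#' @export
ld_from_genotypes <- function(dosages, snp_ids = NULL) {
  dosages <- as.matrix(dosages)
  snp_ids <- snp_ids %||% colnames(dosages)
  if (is.null(snp_ids)) stop_domain("dosage matrix needs SNP column names or snp_ids")
  if (nrow(dosages) < 2L) stop_domain("need at least two individuals to estimate LD")
  r <- suppressWarnings(stats::cor(dosages))
  if (any(!is.finite(r))) stop_domain("monomorphic SNP(s): correlation undefined")
  dimnames(r) <- list(snp_ids, snp_ids)
  new_ld_source("genotypes", r^2, snp_ids, r_signed = r)
}

# r^2 between the SNPs at integer indices i and j of ld$snp_ids.
# For declared-window table sources the caller decides whether an absent
# pair is unknown (within window) or zero; this accessor just reports the
# stored value, with `known` FALSE for structural zeros of incomplete
# tables.
ld_query <- function(ld, i, j) {
  v <- ld$r2[i, j]
  known <- ld$complete | v != 0
  list(r2 = as.numeric(v), known = known)
}

ld_index <- function(ld, snp_ids) {
  idx <- match(snp_ids, ld$snp_ids)
  if (anyNA(idx)) {
    stop_domain("SNP(s) absent from the LD source: ",
                paste(utils::head(snp_ids[is.na(idx)], 5), collapse = ", "))
  }
  idx
}
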