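# Reading and validating per-trait GWAS summary statistics.

SUMMARY_STAT_COLS <- c("snp_id", "chrom", "pos", "effect_allele",
                       "other_allele", "beta", "se", "pval")

#' Construct a validated per-trait summary-statistics table
#'
#' A `summary_stats` object is a data frame with one row per variant and the
#' canonical columns `snp_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `beta`, `se`, `pval`, carrying the trait identifier as an
#' attribute. Rows with non-positive or missing standard errors, missing
#' betas, or p-values outside (0, 1] are dropped; the number of dropped rows
#' is recorded in the `n_dropped` attribute.
#'
#' @param trait_id Single string identifying the trait (e.g. an IDP name).
#' @param data Data frame with the canonical columns.
#' @return A `summary_stats` data frame.
#' @export
summary_stats <- function(trait_id, data) {
  stopifnot(is.character(trait_id), length(trait_id) == 1L)
  missing_cols <- setdiff(SUMMARY_STAT_COLS, names(data))
  if (length(missing_cols)) {
    stop_format("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  data <- as.data.frame(data)[SUMMARY_STAT_COLS]
  data$snp_id <- as.character(data$snp_id)
  data$chrom <- as.character(data$chrom)
  data$pos <- as.integer(data$pos)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  data$beta <- as.numeric(data$beta)
  data$se <- as.numeric(data$se)
  data$pval <- as.numeric(data$pval)

  keep <- is.finite(data$beta) & is.finite(data$se) & data$se > 0 &
    is.finite(data$pval) & data$pval > 0 & data$pval <= 1
  n_dropped <- sum(!keep)
  data <- data[keep, , drop = FALSE]
  if (nrow(data) == 0L) {
    stop_format("no rows survive validation for trait '", trait_id, "'")
  }
  if (anyDuplicated(data$snp_id)) {
    dup <- unique(data$snp_id[duplicated(data$snp_id)])
    stop_format("duplicated snp_id in trait '", trait_id, "': ",
                paste(utils::head(dup, 5), collapse = ", "))
  }
  rownames(data) <- NULL
  structure(data,
            trait_id = trait_id,
            n_dropped = n_dropped,
            class = c("summary_stats", "data.frame"))
}

#' Trait identifier of a summary-statistics table
#' @param x A `summary_stats` object.
#' @return The trait id string.
#' @export
trait_id <- function(x) attr(x, "trait_id")

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics for trait '%s': %d variants (%d dropped at read)\n",
              trait_id(x), nrow(x), attr(x, "n_dropped") %||% 0L))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Read one trait's GWAS summary statistics from a delimited text file
#'
#' Reads a whitespace- or tab-delimited file with a header (optionally
#' gzip-compressed), renames columns to the canonical schema via
#' `column_map`, converts `-log10(p)` columns back to p-values when
#' `pval_scale = "neglog10p"`, and validates the result (see
#' [summary_stats()] for the row-dropping rules).
#'
#' @param path Path to the file.
#' @param trait_id Trait identifier; defaults to the file name without
#'   extension.
#' @param column_map Named character vector mapping canonical names
#'   (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`,
#'   `se`, `pval`) to column names in the file. Canonical names missing from
#'   the map are looked up verbatim.
#' @param pval_scale `"p"` for plain p-values, `"neglog10p"` for -log10(p)
#'   (the distribution format of some GWAS databases).
#' @return A [summary_stats()] object; dropped-row count in attribute
#'   `n_dropped`.
#' @export
read_summary_stats <- function(path, trait_id = NULL, column_map = NULL,
                               pval_scale = c("p", "neglog10p")) {
  pval_scale <- match.arg(pval_scale)
  if (!file.exists(path)) stop_format("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  raw <- utils::read.table(con, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "")
  map <- stats::setNames(SUMMARY_STAT_COLS, SUMMARY_STAT_COLS)
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  missing_cols <- map[!(map %in% names(raw))]
  if (length(missing_cols)) {
    stop_format("missing mandatory column(s) in ", path, ": ",
                paste(sprintf("%s (mapped from %s)", missing_cols, names(missing_cols)),
                      collapse = ", "))
  }
  data <- raw[unname(map)]
  names(data) <- names(map)
  if (pval_scale == "neglog10p") data$pval <- 10^(-as.numeric(data$pval))
  if (is.null(trait_id)) {
    trait_id <- sub("\\.(tsv|txt|csv)(\\.gz)?$", "", basename(path))
  }
  summary_stats(trait_id, data)
}

#' Standard-error scaled z-value of a GWAS effect size
#'
#' @param beta Effect size(s).
#' @param se Standard error(s), strictly positive.
#' @return `beta / se`, vectorized.
#' @export
z_transform <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop_domain("standard errors must be finite and strictly positive")
  }
  beta / se
}
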