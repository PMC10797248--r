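# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Deterministic ordering rank for chromosome labels: 1..22, X=23, Y=24,
# MT/M=25, anything else after, alphabetically. Needed because chromosomes
# are stored as strings (to admit X/MT) but pruning/clumping scan in
# genomic order.
chrom_rank <- function(chrom) {
  chrom <- toupper(as.character(chrom))
  chrom <- sub("^CHR", "", chrom)
  r <- suppressWarnings(as.numeric(chrom))
  r[chrom == "X"] <- 23
  r[chrom == "Y"] <- 24
  r[chrom %in% c("MT", "M")] <- 25
  bad <- is.na(r)
  if (any(bad)) {
    extra <- sort(unique(chrom[bad]))
    r[bad] <- 25 + match(chrom[bad], extra)
  }
  r
}

genomic_order <- function(chrom, pos) order(chrom_rank(chrom), pos)

stop_domain <- function(...) {
  stop(structure(class = c("gwasdecomp_domain_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("gwasdecomp_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Skewness without bias correction; used only for sign conventions.
row_skewness <- function(x) {
  mu <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)
  mean((x - mu)^3) / s^3
}

# Full-precision numeric formatting so TSV round trips are bit-identical.
format_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
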