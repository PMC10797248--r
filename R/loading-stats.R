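# Per-SNP significance of component loadings and Manhattan-ready tables.

#' Normal-CDF significance of component SNP loadings
#'
#' Standardizes a component's loading vector by its own mean and standard
#' deviation and converts each loading to a p-value under a Gaussian
#' reference: one-tailed `1 - pnorm(z)` (upper tail) or two-tailed
#' `2 * pnorm(-|z|)` (default). Invariant to affine rescaling of the
#' whole vector.
#'
#' @param loadings Numeric vector (>= 3 finite values).
#' @param tails `"two"` (default) or `"one"`.
#' @return Numeric vector of p-values in (0, 1].
#' @export
loading_significance <- function(loadings, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (length(loadings) < 3L || any(!is.finite(loadings))) {
    stop_domain("need at least 3 finite loadings")
  }
  mu <- mean(loadings); sdv <- stats::sd(loadings)
  if (sdv == 0) stop_domain("degenerate loading vector (zero standard deviation)")
  z <- (loadings - mu) / sdv
  if (tails == "one") stats::pnorm(z, lower.tail = FALSE) else 2 * stats::pnorm(-abs(z))
}

#' Manhattan-style significance table for one component
#'
#' Joins a component's SNP loadings to genomic coordinates, attaches
#' normal-CDF p-values and a -log10(p) column, ordered by (chromosome,
#' position) — the plot-ready table behind Manhattan-like component
#' summaries.
#'
#' @param d A `decomposition` whose registry carries coordinates.
#' @param component Component index (1..K).
#' @param tails Tail convention for [loading_significance()].
#' @return Data frame `(snp_id, chrom, pos, component, loading, p,
#'   neg_log10_p)`.
#' @export
manhattan_table <- function(d, component, tails = c("two", "one")) {
  stopifnot(inherits(d, "decomposition"))
  tails <- match.arg(tails)
  if (!(length(component) == 1L && component == round(component) &&
        component >= 1 && component <= d$K)) {
    stop_domain("component index out of range [1, ", d$K, "]")
  }
  reg <- d$snp_registry
  miss <- !is.finite(suppressWarnings(as.numeric(reg$pos))) | is.na(reg$chrom)
  if (any(miss)) {
    stop_domain("registry lacks coordinates for SNP(s): ",
                paste(utils::head(reg$snp_id[miss], 10), collapse = ", "))
  }
  loading <- d$snp_loadings[component, ]
  p <- loading_significance(loading, tails)
  out <- data.frame(snp_id = reg$snp_id, chrom = reg$chrom, pos = reg$pos,
                    component = as.integer(component),
                    loading = as.numeric(loading), p = p,
                    neg_log10_p = -log10(p), stringsAsFactors = FALSE)
  out <- out[genomic_order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
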