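# Selection of qualified cis instruments per protein: cis window around the
# encoding gene, genome-wide significance, greedy LD clumping, variance
# explained, and F-statistic weak-instrument filtering.

#' Restrict variants to the cis window of a gene
#'
#' Retains variants on the gene's chromosome whose position falls within
#' `window_bp` of the gene body (start - window, end + window, 1-based
#' inclusive). cis-pQTLs are conventionally defined within 1 Mb of the
#' encoding gene.
#'
#' @param records Variant record data frame (`chrom`, `pos` required).
#' @param gene List or one-row data frame with `gene_id`, `chrom`, `start`,
#'   `end` (1-based inclusive, `start <= end`).
#' @param window_bp Window size in base pairs (default 1e6).
#' @return Subset of `records`; empty data frame when nothing qualifies.
#' @export
select_cis <- function(records, gene, window_bp = 1e6) {
  if (gene$start > gene$end) stop("gene start must be <= end", call. = FALSE)
  keep <- records$chrom == gene$chrom &
    records$pos >= gene$start - window_bp &
    records$pos <= gene$end + window_bp
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter variants by association p-value
#'
#' Strict inequality: a variant at exactly the threshold is dropped,
#' matching the genome-wide significance convention p < 5e-8.
#'
#' @param records Variant record data frame with `pval`.
#' @param threshold Significance threshold (default 5e-8).
#' @return Subset of `records`.
#' @export
filter_pvalue <- function(records, threshold = 5e-8) {
  out <- records[records$pval < threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Clumping parameter presets
#'
#' `"methods"` is the default working preset (r-squared < 0.1 within
#' 1000 kb); `"stringent"` is a conservative preset sometimes used to
#' enforce near-independence of instruments (r-squared < 0.001 within
#' 10,000 kb).
#'
#' @param name Preset name.
#' @return List with `r2_threshold` and `window_kb`.
#' @export
clump_preset <- function(name = c("methods", "stringent")) {
  switch(match.arg(name),
         methods = list(r2_threshold = 0.1, window_kb = 1000),
         stringent = list(r2_threshold = 0.001, window_kb = 10000))
}

#' Greedy LD clumping
#'
#' Repeatedly takes the remaining variant with the smallest p-value (ties
#' broken by smaller position, then lexicographic id), keeps it, and
#' removes all remaining variants within `window_kb` of it whose squared
#' correlation with it is at least `r2_threshold`. The kept set is returned
#' in selection order.
#'
#' @param records Variant record data frame (`variant_id`, `pos`, `pval`).
#' @param ld Square correlation matrix (signed r) with variant ids as
#'   dimnames; symmetric with unit diagonal. Every record's id must be
#'   present.
#' @param r2_threshold Squared-correlation pruning threshold (default 0.1).
#' @param window_kb Physical window in kilobases (default 1000).
#' @return Subset of `records` in selection order.
#' @export
ld_clump <- function(records, ld, r2_threshold = 0.1, window_kb = 1000) {
  if (nrow(records) == 0L) return(records)
  ids <- records$variant_id
  missing <- setdiff(ids, rownames(ld))
  if (length(missing))
    stop("variant(s) missing from LD matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ord <- order(records$pval, records$pos, records$variant_id)
  remaining <- ord
  kept <- integer(0)
  window_bp <- window_kb * 1000
  while (length(remaining)) {
    lead <- remaining[1L]
    kept <- c(kept, lead)
    remaining <- remaining[-1L]
    if (!length(remaining)) break
    close_by <- abs(records$pos[remaining] - records$pos[lead]) <= window_bp
    r2 <- ld[records$variant_id[remaining], records$variant_id[lead]]^2
    remaining <- remaining[!(close_by & r2 >= r2_threshold)]
  }
  out <- records[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Variance in the exposure explained by one variant
#'
#' `R^2 = 2 * EAF * (1 - EAF) * beta^2` for a per-allele effect on a
#' standardized trait under Hardy-Weinberg equilibrium.
#'
#' @param eaf Effect-allele frequency in (0, 1).
#' @param beta Per-allele effect.
#' @return Variance explained (fraction). Vectorized.
#' @export
variance_explained <- function(eaf, beta) {
  if (any(eaf <= 0 | eaf >= 1)) stop("eaf must be in (0,1)", call. = FALSE)
  2 * eaf * (1 - eaf) * beta^2
}

#' Instrument-strength F-statistic
#'
#' `"standard"` uses the conventional two-stage-least-squares approximation
#' `F = R2 (N - K - 1) / ((1 - R2) K)`. `"as_printed"` substitutes
#' `(1 + R2)` in the denominator, a variant occasionally seen in the
#' applied literature; it is exposed for auditability and gives slightly
#' smaller values.
#'
#' @param r2 Variance explained by the instrument(s), in \[0, 1).
#' @param n Sample size; must exceed `k + 1`.
#' @param k Number of instruments in the model (1 for a per-variant F).
#' @param formula_variant `"standard"` or `"as_printed"`.
#' @return F-statistic. Vectorized over `r2`.
#' @export
f_statistic <- function(r2, n, k = 1,
                        formula_variant = c("standard", "as_printed")) {
  formula_variant <- match.arg(formula_variant)
  if (any(k < 1)) stop("k must be >= 1", call. = FALSE)
  if (any(n <= k + 1)) stop("n must exceed k + 1", call. = FALSE)
  denom <- switch(formula_variant, standard = 1 - r2, as_printed = 1 + r2)
  r2 * (n - k - 1) / (denom * k)
}

#' Per-variant and overall instrument strength
#'
#' Computes each variant's variance explained and per-variant F (k = 1),
#' plus the overall F using k = number of instruments and R-squared equal
#' to the sum of per-variant contributions. Weak-instrument filtering is
#' done on the per-variant F.
#'
#' @param pairs Harmonized pairs (needs `eaf_exp`, `beta_exp`, `n_exp`).
#' @param formula_variant Passed to [f_statistic()].
#' @return Data frame with `variant_id`, `r2`, `f_stat`, `k`, `n`;
#'   attributes `r2_total` and `f_overall`.
#' @export
instrument_stats <- function(pairs, formula_variant = "standard") {
  r2 <- variance_explained(pairs$eaf_exp, pairs$beta_exp)
  out <- data.frame(variant_id = pairs$variant_id, r2 = r2,
                    f_stat = f_statistic(r2, pairs$n_exp, 1, formula_variant),
                    k = 1L, n = pairs$n_exp, stringsAsFactors = FALSE)
  k_all <- nrow(pairs)
  attr(out, "r2_total") <- sum(r2)
  attr(out, "f_overall") <-
    if (k_all >= 1 && all(pairs$n_exp > k_all + 1))
      f_statistic(sum(r2), pairs$n_exp[1], k_all, formula_variant)
    else NA_real_
  out
}

#' Drop weak instruments
#'
#' Keeps instruments with `f_stat` strictly greater than `f_min`
#' (conventionally 10). An empty result means the protein has no qualified
#' instrument and is excluded from MR by the caller.
#'
#' @param instruments Data frame with an `f_stat` column (e.g.
#'   [instrument_stats()] output, or harmonized pairs with `f_stat`
#'   merged in).
#' @param f_min Strict lower bound (default 10).
#' @return Subset of `instruments`.
#' @export
filter_weak <- function(instruments, f_min = 10) {
  out <- instruments[instruments$f_stat > f_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a square LD matrix from TSV
#'
#' Expects a header row of variant ids and a first column of variant ids;
#' entries are signed correlations.
#'
#' @param path TSV path.
#' @return Numeric matrix with dimnames.
#' @export
read_ld_matrix <- function(path) {
  raw <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    row.names = 1)
  m <- as.matrix(raw)
  if (nrow(m) != ncol(m)) stop("LD matrix must be square", call. = FALSE)
  m
}

#' Write a square LD matrix as TSV
#'
#' @param ld Matrix with dimnames.
#' @param path Output path.
#' @export
write_ld_matrix <- function(ld, path) {
  df <- data.frame(variant_id = rownames(ld), ld, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
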