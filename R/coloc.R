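# Five-hypothesis Bayesian colocalization of two traits at a locus from
# summary statistics, via Wakefield-style approximate Bayes factors under
# the single-causal-variant-per-trait assumption.
#
# Hypotheses: H0 no association with either trait; H1/H2 association with
# one trait only; H3 both traits, distinct causal variants; H4 both
# traits, a shared causal variant.

#' Per-variant log approximate Bayes factor
#'
#' Wakefield's approximate Bayes factor for association at one variant:
#' with `z = beta/se`, `V = se^2` and shrinkage `r = W/(W + V)` where
#' `W = prior_sd_w^2` is the prior variance of a true effect,
#' `log ABF = 0.5 log(1 - r) + 0.5 r z^2`.
#'
#' @param beta,se Per-variant effect and standard error (`se > 0`).
#' @param prior_sd_w Prior SD of a true effect: conventionally 0.15 for
#'   quantitative traits (SD units) and 0.2 for case-control traits
#'   (log-odds).
#' @return Numeric vector of log ABFs.
#' @export
log_abf <- function(beta, se, prior_sd_w = 0.15) {
  if (any(se <= 0)) stop("se must be positive", call. = FALSE)
  w <- prior_sd_w^2
  v <- se^2
  r <- w / (w + v)
  0.5 * log1p(-r) + 0.5 * r * (beta / se)^2
}

# Default ABF prior SD by trait type.
abf_prior_sd <- function(trait_type) {
  switch(trait_type, quantitative = 0.15, case_control = 0.2,
         stop("unknown trait_type: ", trait_type, call. = FALSE))
}

#' Bayesian colocalization of two traits at a locus
#'
#' Enumerates the single-causal-variant configurations for the two traits
#' over the intersection of their variants, combining per-variant log ABFs
#' with prior probabilities `p1`, `p2` (trait-specific causal variant) and
#' `p12` (shared causal variant). All sums are done in log space with
#' log-sum-exp; the H3 (distinct variants) term is the log-difference
#' `sum_i ABF1_i * sum_j ABF2_j - sum_i ABF1_i * ABF2_i`.
#'
#' @param d1,d2 Locus datasets: lists with `variant_ids`, `beta`, `se`
#'   (equal-length vectors) and `trait_type` (`"quantitative"` or
#'   `"case_control"`, which sets the ABF prior SD unless `prior_sd1` /
#'   `prior_sd2` is given).
#' @param p1,p2,p12 Prior probabilities that a variant is causal for trait
#'   1 only, trait 2 only, or both (defaults 1e-4, 1e-4, 1e-5).
#' @param prior_sd1,prior_sd2 Optional overrides of the per-trait ABF
#'   prior SD.
#' @return List of class `coloc_result` with `pp0`..`pp4` (summing to 1),
#'   `n_snps`, and `priors`.
#' @export
coloc_abf <- function(d1, d2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd1 = NULL, prior_sd2 = NULL) {
  common <- intersect(d1$variant_ids, d2$variant_ids)
  if (!length(common)) stop("no shared variants between datasets",
                            call. = FALSE)
  i1 <- match(common, d1$variant_ids)
  i2 <- match(common, d2$variant_ids)
  sd1 <- if (is.null(prior_sd1)) abf_prior_sd(d1$trait_type) else prior_sd1
  sd2 <- if (is.null(prior_sd2)) abf_prior_sd(d2$trait_type) else prior_sd2
  l1 <- log_abf(d1$beta[i1], d1$se[i1], sd1)
  l2 <- log_abf(d2$beta[i2], d2$se[i2], sd2)

  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls12 <- logsumexp(l1 + l2)
  lh3 <- if (length(common) >= 2L) logdiff(ls1 + ls2, ls12) else -Inf

  lp <- c(h0 = 0,
          h1 = log(p1) + ls1,
          h2 = log(p2) + ls2,
          h3 = log(p1) + log(p2) + lh3,
          h4 = log(p12) + ls12)
  pp <- exp(lp - logsumexp(lp))
  structure(list(pp0 = pp[["h0"]], pp1 = pp[["h1"]], pp2 = pp[["h2"]],
                 pp3 = pp[["h3"]], pp4 = pp[["h4"]],
                 n_snps = length(common),
                 priors = c(p1 = p1, p2 = p2, p12 = p12)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "<coloc_result> %d SNPs  PP0 %.3f  PP1 %.3f  PP2 %.3f  PP3 %.3f  PP4 %.3f\n",
    x$n_snps, x$pp0, x$pp1, x$pp2, x$pp3, x$pp4))
  invisible(x)
}

#' Convert variant records to a locus dataset
#'
#' Builds the list structure consumed by [coloc_abf()] from a variant
#' record data frame (e.g. read back from TSV with [read_sumstats()]).
#'
#' @param records Record data frame with `variant_id`, `beta`, `se` and a
#'   `trait_type` column (or supply `trait_type` explicitly).
#' @param trait_type Optional override of the records' trait type.
#' @return List with `variant_ids`, `beta`, `se`, `trait_type`.
#' @export
as_locus_dataset <- function(records, trait_type = NULL) {
  if (is.null(trait_type)) trait_type <- records$trait_type[1L]
  list(variant_ids = records$variant_id, beta = records$beta,
       se = records$se, trait_type = trait_type)
}

#' Classify a colocalization result
#'
#' Evidence of a shared causal variant iff `pp4` strictly exceeds the
#' threshold (conventionally 0.80).
#'
#' @param result `coloc_result` (or anything with a `pp4` element).
#' @param pp4_threshold Strict threshold (default 0.80).
#' @return Logical.
#' @export
classify_coloc <- function(result, pp4_threshold = 0.80) {
  result$pp4 > pp4_threshold
}
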