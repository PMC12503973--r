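# Summary-data-based MR (SMR) at the top cis variant, with the HEIDI
# (heterogeneity in dependent instruments) test separating a single shared
# causal variant (causality/pleiotropy) from linkage of distinct variants.

#' SMR test at the top QTL variant
#'
#' `b_smr = b_gwas / b_qtl` with the test statistic
#' `T = z_gwas^2 z_qtl^2 / (z_gwas^2 + z_qtl^2)` referred to chi-square
#' with 1 df, and `se_smr = |b_smr| / sqrt(T)`.
#'
#' @param z_qtl,z_gwas Z statistics of the QTL and GWAS associations at
#'   the top variant.
#' @param b_qtl,b_gwas Effect sizes at the top variant (`b_qtl != 0`).
#' @return List with `b_smr`, `se_smr`, `p_smr`, `t_smr`.
#' @export
smr_test <- function(z_qtl, z_gwas, b_qtl, b_gwas) {
  if (b_qtl == 0) stop("b_qtl must be nonzero", call. = FALSE)
  b_smr <- b_gwas / b_qtl
  t_smr <- if (z_gwas == 0 && z_qtl == 0) 0
           else z_gwas^2 * z_qtl^2 / (z_gwas^2 + z_qtl^2)
  p_smr <- clamp_pval(pchisq(t_smr, df = 1, lower.tail = FALSE))
  se_smr <- if (t_smr > 0) abs(b_smr) / sqrt(t_smr) else Inf
  list(b_smr = b_smr, se_smr = se_smr, p_smr = p_smr, t_smr = t_smr)
}

#' Select variants for the HEIDI test
#'
#' Picks variants whose squared correlation with the top variant lies in
#' `[r2_min, r2_max]` and whose QTL association satisfies `z^2 > z2_min`
#' (the instrument convention z^2 > 10, i.e. p < 1.57e-3), truncated to
#' the `max_snps` variants with the highest r-squared. The top variant
#' itself is excluded from the test set.
#'
#' @param pairs Harmonized locus pairs (needs `variant_id`, `beta_exp`,
#'   `se_exp`).
#' @param ld Signed correlation matrix with variant ids as dimnames.
#' @param top_id Top variant id; defaults to the largest QTL z-squared.
#' @param r2_min,r2_max LD eligibility window (defaults 0.05, 0.9).
#' @param max_snps Cap on the test set size (default 20).
#' @param z2_min QTL instrument threshold (default 10).
#' @return Character vector of selected variant ids (may be shorter than
#'   3, in which case HEIDI is not applicable).
#' @export
heidi_select <- function(pairs, ld, top_id = NULL, r2_min = 0.05,
                         r2_max = 0.9, max_snps = 20, z2_min = 10) {
  z2 <- (pairs$beta_exp / pairs$se_exp)^2
  if (is.null(top_id)) top_id <- pairs$variant_id[which.max(z2)]
  others <- pairs$variant_id != top_id
  r2 <- ld[pairs$variant_id, top_id]^2
  eligible <- others & r2 >= r2_min & r2 <= r2_max & z2 > z2_min
  ids <- pairs$variant_id[eligible]
  if (length(ids) > max_snps)
    ids <- ids[order(r2[eligible], decreasing = TRUE)][seq_len(max_snps)]
  ids
}

#' HEIDI heterogeneity test
#'
#' Tests whether SMR ratio estimates at LD partners of the top variant are
#' consistent with a single shared causal variant. For each selected
#' variant `d_i = b_smr(i) - b_smr(top)`; the covariance of the `d` vector
#' is propagated from the GWAS and QTL sampling errors and the LD
#' correlations by the delta method. The statistic `sum z_d^2` is referred
#' to a correlated chi-square sum via the eigenvalues of the correlation
#' matrix of `z_d`, with the tail probability by Satterthwaite-Welch
#' two-moment matching (scaled chi-square). A small p-value indicates
#' linkage of distinct causal variants rather than a shared one.
#'
#' @param pairs Harmonized locus pairs (all variants at the locus).
#' @param ld Signed correlation matrix with variant ids as dimnames.
#' @param top_id Top variant id; defaults to the largest QTL z-squared.
#' @param selected Variant ids to test; defaults to [heidi_select()].
#' @return List with `p_heidi`, `stat`, `n_heidi_snps`, `top_variant_id`;
#'   `p_heidi` is NA with a `reason` when fewer than 3 variants are
#'   eligible.
#' @export
heidi_test <- function(pairs, ld, top_id = NULL, selected = NULL) {
  z2 <- (pairs$beta_exp / pairs$se_exp)^2
  if (is.null(top_id)) top_id <- pairs$variant_id[which.max(z2)]
  if (is.null(selected)) selected <- heidi_select(pairs, ld, top_id)
  if (length(selected) < 3L)
    return(list(p_heidi = NA_real_, stat = NA_real_,
                n_heidi_snps = length(selected), top_variant_id = top_id,
                reason = "fewer than 3 eligible variants"))
  ids <- c(selected, top_id)
  rows <- match(ids, pairs$variant_id)
  u <- pairs$beta_out[rows]; su <- pairs$se_out[rows]   # GWAS
  v <- pairs$beta_exp[rows]; sv <- pairs$se_exp[rows]   # QTL
  r <- ld[ids, ids]
  b <- u / v
  # delta-method covariance of the ratio estimates; GWAS and QTL samples
  # are independent, so the two variance components add
  cb <- r * outer(su, su) / outer(v, v) +
    r * outer(sv, sv) * outer(u, u) / outer(v^2, v^2)
  m <- length(selected)
  t_idx <- m + 1L
  d <- b[seq_len(m)] - b[t_idx]
  vd <- cb[seq_len(m), seq_len(m), drop = FALSE] -
    matrix(cb[seq_len(m), t_idx], m, m) -
    matrix(cb[t_idx, seq_len(m)], m, m, byrow = TRUE) + cb[t_idx, t_idx]
  vd <- (vd + t(vd)) / 2
  ev <- eigen(vd, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(abs(ev))) {
    warning("HEIDI covariance near-singular; ridge-regularizing diagonal")
    vd <- vd + diag(1e-8, m)
  }
  sdd <- sqrt(diag(vd))
  z_d <- d / sdd
  corr <- vd / outer(sdd, sdd)
  stat <- sum(z_d^2)
  lambda <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  s1 <- sum(lambda); s2 <- sum(lambda^2)
  scale_c <- s2 / s1
  df_nu <- s1^2 / s2
  p <- clamp_pval(pchisq(stat / scale_c, df = df_nu, lower.tail = FALSE))
  list(p_heidi = p, stat = stat, n_heidi_snps = m, top_variant_id = top_id)
}

#' SMR + HEIDI analysis of one locus
#'
#' Picks the top variant (smallest QTL p-value, i.e. largest z-squared),
#' runs the SMR test there, and the HEIDI test over its LD partners.
#'
#' @param pairs Harmonized locus pairs.
#' @param ld Signed correlation matrix.
#' @param ... Passed to [heidi_select()].
#' @return List with `top_variant_id`, `b_smr`, `se_smr`, `p_smr`,
#'   `p_heidi`, `n_heidi_snps`.
#' @export
smr_analysis <- function(pairs, ld, ...) {
  z_qtl <- pairs$beta_exp / pairs$se_exp
  top <- which.max(z_qtl^2)
  top_id <- pairs$variant_id[top]
  smr <- smr_test(z_qtl[top], pairs$beta_out[top] / pairs$se_out[top],
                  pairs$beta_exp[top], pairs$beta_out[top])
  selected <- heidi_select(pairs, ld, top_id, ...)
  heidi <- heidi_test(pairs, ld, top_id, selected)
  list(top_variant_id = top_id, b_smr = smr$b_smr, se_smr = smr$se_smr,
       p_smr = smr$p_smr, p_heidi = heidi$p_heidi,
       n_heidi_snps = heidi$n_heidi_snps)
}

#' Classify an SMR + HEIDI result
#'
#' Passed iff `p_smr < 0.05 / m_tests` (Bonferroni over the proteins
#' tested by SMR, strict) and `p_heidi > 0.05` (no evidence that the
#' association is driven by LD). An undefined HEIDI p fails with a reason.
#'
#' @param p_smr SMR p-value.
#' @param m_tests Number of SMR tests in the family.
#' @param p_heidi HEIDI p-value (NA when not applicable).
#' @param alpha Family-wise level for SMR and the HEIDI cutoff
#'   (default 0.05).
#' @return List with `passed` (logical) and `reason`.
#' @export
classify_smr <- function(p_smr, m_tests, p_heidi, alpha = 0.05) {
  if (is.na(p_heidi))
    return(list(passed = FALSE, reason = "HEIDI not applicable"))
  if (!(p_smr < alpha / m_tests))
    return(list(passed = FALSE, reason = "SMR not significant"))
  if (!(p_heidi > alpha))
    return(list(passed = FALSE, reason = "HEIDI indicates linkage"))
  list(passed = TRUE, reason = "passed SMR and HEIDI")
}
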