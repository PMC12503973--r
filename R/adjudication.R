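# Diagnostics-driven method adjudication, Bonferroni discovery/replication
# logic, replication consistency, and cross-cohort meta-analysis.

#' Detect heterogeneity and pleiotropy flags from diagnostics
#'
#' Heterogeneity is flagged when Cochran's Q p-value is strictly below
#' `alpha`; pleiotropy when either the MR-Egger intercept p or the
#' MR-PRESSO global p is strictly below `alpha`. Diagnostics that are
#' undefined at the available number of instruments (NA) count as
#' not-detected and are listed in the `missing` attribute for the audit
#' trail.
#'
#' @param diag Diagnostics list as from [mr_diagnostics()].
#' @param alpha Test level (default 0.05).
#' @return Named logical vector `c(heterogeneity, pleiotropy)` with
#'   attribute `missing`.
#' @export
detect_flags <- function(diag, alpha = 0.05) {
  lt <- function(p) !is.na(p) && p < alpha
  missing <- c("cochran_q", "egger_intercept", "presso_global")[
    c(is.na(diag$q_pval), is.na(diag$egger_intercept_pval),
      is.na(diag$presso_global_pval))]
  out <- c(heterogeneity = lt(diag$q_pval),
           pleiotropy = lt(diag$egger_intercept_pval) ||
             lt(diag$presso_global_pval))
  attr(out, "missing") <- missing
  out
}

# Candidate method lists for each flag combination, in tie-break order.
.CANDIDATES <- list(
  none = "ivw_fe",
  heterogeneity = c("weighted_median", "ivw_mre"),
  pleiotropy = c("egger", "presso_corrected"),
  both = c("weighted_median", "ivw_mre", "egger", "presso_corrected"))

#' Choose the primary causal estimate for one protein
#'
#' Implements the diagnostics-driven selection tree: a single instrument
#' forces the Wald ratio; with no flags the (fixed-effect) IVW is primary;
#' under heterogeneity only, the method with the largest p-value among
#' weighted median and multiplicative random-effects IVW; under pleiotropy
#' only, the larger-p of MR-Egger and the MR-PRESSO outlier-corrected
#' estimate; under both, the largest p among all four. Ties take the
#' method listed earlier; methods unavailable at the instrument count are
#' excluded from the candidate set and recorded.
#'
#' @param estimates Named list of [mr_estimate()] objects (names are
#'   method tags: `wald_ratio`, `ivw_fe`, `ivw_mre`, `weighted_median`,
#'   `egger`, `presso_corrected`).
#' @param flags Output of [detect_flags()].
#' @param n_snp Number of instruments.
#' @return List with `primary_method`, `primary_estimate`,
#'   `heterogeneity_detected`, `pleiotropy_detected`,
#'   `candidate_methods_considered`, `excluded_methods`, `inconclusive`.
#' @export
choose_primary <- function(estimates, flags, n_snp) {
  if (n_snp == 1L) {
    candidates <- "wald_ratio"
  } else {
    key <- if (flags[["heterogeneity"]] && flags[["pleiotropy"]]) "both"
      else if (flags[["heterogeneity"]]) "heterogeneity"
      else if (flags[["pleiotropy"]]) "pleiotropy"
      else "none"
    candidates <- .CANDIDATES[[key]]
  }
  available <- vapply(candidates, function(m)
    !is.null(estimates[[m]]) && is.finite(estimates[[m]]$pval), logical(1))
  usable <- candidates[available]
  excluded <- candidates[!available]
  if (!length(usable))
    return(list(primary_method = NA_character_, primary_estimate = NULL,
                heterogeneity_detected = unname(flags[["heterogeneity"]]),
                pleiotropy_detected = unname(flags[["pleiotropy"]]),
                candidate_methods_considered = candidates,
                excluded_methods = excluded, inconclusive = TRUE))
  pvals <- vapply(usable, function(m) estimates[[m]]$pval, numeric(1))
  # which.max returns the first maximum: ties go to the earlier method
  chosen <- usable[which.max(pvals)]
  list(primary_method = chosen, primary_estimate = estimates[[chosen]],
       heterogeneity_detected = unname(flags[["heterogeneity"]]),
       pleiotropy_detected = unname(flags[["pleiotropy"]]),
       candidate_methods_considered = candidates,
       excluded_methods = excluded, inconclusive = FALSE)
}

#' Bonferroni significance flags
#'
#' Significant iff `p < alpha / m` (strict), with `m` the number of tests
#' (e.g. the number of proteins with a valid MR estimate).
#'
#' @param pvals Named numeric vector of p-values.
#' @param m Number of tests (>= 1).
#' @param alpha Family-wise level (default 0.05).
#' @return Named logical vector; NA p-values give FALSE.
#' @export
bonferroni_flag <- function(pvals, m, alpha = 0.05) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  out <- !is.na(pvals) & pvals < alpha / m
  names(out) <- names(pvals)
  out
}

#' Replication consistency and prioritization
#'
#' A protein is prioritized when its discovery estimate is Bonferroni-
#' significant, at least one replication combination is significant after
#' its own Bonferroni correction, and (optionally) every significant
#' replication estimate shares the sign of the discovery estimate. With
#' `mode = "all"`, every replication in which the protein has qualified
#' instruments must be significant.
#'
#' @param discovery List with `significant` (logical) and `beta`.
#' @param replications List of per-combination entries, each either `NULL`
#'   (no qualified instruments in that combination) or a list with
#'   `significant` and `beta`.
#' @param require_direction Require sign agreement of significant
#'   estimates with discovery (default TRUE).
#' @param mode `"any"` (default) or `"all"`.
#' @return List with `prioritized` (logical) and `reason`.
#' @export
replication_consistency <- function(discovery, replications,
                                    require_direction = TRUE,
                                    mode = c("any", "all")) {
  mode <- match.arg(mode)
  if (!isTRUE(discovery$significant))
    return(list(prioritized = FALSE, reason = "discovery not significant"))
  present <- Filter(Negate(is.null), replications)
  if (!length(present))
    return(list(prioritized = FALSE, reason = "no replication instruments"))
  sig <- vapply(present, function(r) isTRUE(r$significant), logical(1))
  passed <- if (mode == "any") any(sig) else all(sig)
  if (!passed)
    return(list(prioritized = FALSE,
                reason = "replication not significant"))
  if (require_direction) {
    betas <- vapply(present[sig], function(r) r$beta, numeric(1))
    if (any(sign(betas) != sign(discovery$beta)))
      return(list(prioritized = FALSE,
                  reason = "direction inconsistent with discovery"))
  }
  list(prioritized = TRUE, reason = "replicated")
}

#' Fixed-effect meta-analysis of MR estimates
#'
#' Inverse-variance pooling on the log-OR scale: pooled beta is the
#' weighted mean with weights `1/se^2`, pooled SE is
#' `(sum 1/se^2)^{-1/2}`. A single estimate passes through with a warning.
#'
#' @param estimates List of [mr_estimate()] objects (log-OR scale).
#' @return [mr_estimate()] with method `"meta_fixed"`.
#' @export
meta_fixed <- function(estimates) {
  estimates <- Filter(function(e) is.finite(e$beta) && is.finite(e$se),
                      estimates)
  if (!length(estimates)) stop("no estimates to pool", call. = FALSE)
  if (length(estimates) == 1L) {
    warning("meta_fixed: single estimate, passing through")
    est <- estimates[[1L]]
    out <- mr_estimate("meta_fixed", est$beta, est$se, n_snp = est$n_snp,
                       extras = list(n_studies = 1L))
    return(out)
  }
  b <- vapply(estimates, `[[`, numeric(1), "beta")
  se <- vapply(estimates, `[[`, numeric(1), "se")
  w <- 1 / se^2
  beta <- sum(w * b) / sum(w)
  mr_estimate("meta_fixed", beta, 1 / sqrt(sum(w)),
              n_snp = max(vapply(estimates, `[[`, integer(1), "n_snp")),
              extras = list(n_studies = length(estimates)))
}
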