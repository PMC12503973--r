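# Summary-level simulator with known ground truth. Generates paired pQTL
# (quantitative) and disease-GWAS (log-odds) summary statistics under a
# shared AR(1) LD structure and controllable causal architecture, so every
# pipeline stage is testable without individual-level data.
#
# Model: standardized genotypes with correlation matrix R; joint causal
# effects b give marginal expectations R b; marginal estimates are drawn
# from MVN(R b, R / n_eff) with per-variant SE 1/sqrt(n_eff), where
# n_eff = n for quantitative traits and n * cf * (1 - cf) for case-control
# traits on the log-odds scale. Default cohort sizes mirror a large
# proteomics discovery cohort (n = 54,219) and a biobank case-control GWAS
# (n = 306,075 with 7589 cases).

.DEFAULT_N_EXP <- 54219
.DEFAULT_N_OUT <- 306075
.DEFAULT_CASE_FRACTION <- 7589 / 306075

#' AR(1) LD correlation matrix
#'
#' Entry (i, j) is `rho^|i-j|`: positive definite for `|rho| < 1`, a
#' reasonable stand-in for the decaying LD of a local region.
#'
#' @param m Number of variants (>= 1).
#' @param rho AR(1) parameter, `|rho| < 1`.
#' @return m x m correlation matrix (no dimnames).
#' @export
make_ld <- function(m, rho) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  rho^abs(outer(seq_len(m), seq_len(m), `-`))
}

#' Scenario ground truth
#'
#' Describes one simulated locus: the causal architecture (`H0_null`,
#' `H1_protein_only`, `H2_disease_only`, `H3_linkage`, `H4_shared`), the
#' causal variant index per trait, the causal protein-on-disease effect
#' `gamma` (log-OR per SD; used under H4 when not NULL), target top
#' z-scores, pleiotropy parameters and the seed. H4 requires the same
#' causal variant for both traits, H3 distinct ones.
#'
#' @param architecture Architecture label.
#' @param causal_exp,causal_out Causal variant index (1-based) per trait;
#'   defaults place them mid-locus (distinct under H3).
#' @param gamma Causal effect of protein on disease; `NULL` means the
#'   outcome signal (if any) is set from `z_out` instead.
#' @param z_exp,z_out Target top z-scores used to size the causal effects.
#' @param pleiotropy_mean,pleiotropy_sd Direct (not through the protein)
#'   effect at the shared variant.
#' @param seed RNG seed recorded with the scenario.
#' @return List of class `scenario_truth`.
#' @export
scenario_truth <- function(architecture = c("H4_shared", "H0_null",
                                            "H1_protein_only",
                                            "H2_disease_only",
                                            "H3_linkage"),
                           causal_exp = NULL, causal_out = NULL,
                           gamma = NULL, z_exp = 10, z_out = 8,
                           pleiotropy_mean = 0, pleiotropy_sd = 0,
                           seed = 1L) {
  architecture <- match.arg(architecture)
  truth <- list(architecture = architecture, causal_exp = causal_exp,
                causal_out = causal_out, gamma = gamma, z_exp = z_exp,
                z_out = z_out, pleiotropy_mean = pleiotropy_mean,
                pleiotropy_sd = pleiotropy_sd, seed = seed)
  class(truth) <- "scenario_truth"
  truth
}

# Resolve default causal positions for an m-variant locus.
resolve_causals <- function(truth, m) {
  ce <- truth$causal_exp
  co <- truth$causal_out
  arch <- truth$architecture
  if (arch %in% c("H1_protein_only", "H3_linkage", "H4_shared") &&
      is.null(ce)) ce <- max(1L, round(m / 3))
  if (arch == "H4_shared") co <- ce
  if (arch == "H2_disease_only" && is.null(co)) co <- max(1L, round(m / 3))
  if (arch == "H3_linkage" && is.null(co)) co <- min(m, ce + 3L)
  if (arch == "H3_linkage" && identical(ce, co))
    stop("H3_linkage requires distinct causal variants", call. = FALSE)
  if (arch == "H0_null") { ce <- NULL; co <- NULL }
  list(causal_exp = ce, causal_out = co)
}

#' Simulate paired summary statistics for one locus
#'
#' Draws exposure (quantitative pQTL) and outcome (case-control GWAS,
#' log-odds) marginal summary statistics for `m` variants under AR(1) LD,
#' according to the scenario's architecture. Under `H4_shared` with a
#' non-NULL `gamma`, the outcome's causal effect at the shared variant is
#' `gamma` times the exposure's causal effect plus the direct-effect term;
#' otherwise outcome signals are sized from `z_out`. Betas and SEs are
#' returned on the per-allele scale (EAF drawn uniform on (0.1, 0.9),
#' shared by both traits); `scale = "standardized"` skips the conversion.
#' Bit-identical outputs for identical (configuration, seed).
#'
#' @param truth [scenario_truth()] object.
#' @param m Number of variants (default 50).
#' @param rho AR(1) LD parameter (default 0.9).
#' @param n_exp,n_out Sample sizes (defaults: the package's discovery
#'   cohort scales).
#' @param case_fraction Outcome case fraction in (0, 1).
#' @param seed RNG seed (defaults to `truth$seed`).
#' @param scale `"per_allele"` or `"standardized"`.
#' @return List with `ld`, `exposure`, `outcome` (locus datasets with
#'   `variant_ids`, `chrom`, `pos`, alleles, `eaf`, `beta`, `se`, `pval`,
#'   `n`, `trait_type`, and `case_fraction` for the outcome) and `truth`
#'   (with resolved causal indices).
#' @export
simulate_locus <- function(truth, m = 50, rho = 0.9,
                           n_exp = .DEFAULT_N_EXP, n_out = .DEFAULT_N_OUT,
                           case_fraction = .DEFAULT_CASE_FRACTION,
                           seed = truth$seed, scale = "per_allele") {
  if (case_fraction <= 0 || case_fraction >= 1)
    stop("case_fraction must be in (0,1)", call. = FALSE)
  ld <- make_ld(m, rho)
  ids <- sprintf("snp_%03d", seq_len(m))
  dimnames(ld) <- list(ids, ids)
  pos <- 1000000L + seq_len(m) * 5000L
  n_eff_exp <- n_exp
  n_eff_out <- n_out * case_fraction * (1 - case_fraction)

  cz <- resolve_causals(truth, m)
  b_exp <- rep(0, m)
  b_out <- rep(0, m)
  if (!is.null(cz$causal_exp))
    b_exp[cz$causal_exp] <- truth$z_exp / sqrt(n_eff_exp)

  sim <- with_seed(seed, {
    direct <- if (truth$pleiotropy_sd > 0)
      rnorm(1, truth$pleiotropy_mean, truth$pleiotropy_sd)
    else truth$pleiotropy_mean
    if (!is.null(cz$causal_out)) {
      b_out[cz$causal_out] <-
        if (truth$architecture == "H4_shared" && !is.null(truth$gamma))
          truth$gamma * b_exp[cz$causal_exp] + direct
        else truth$z_out / sqrt(n_eff_out)
    }
    eaf <- runif(m, 0.1, 0.9)
    bhat_exp <- unname(MASS::mvrnorm(1, mu = drop(ld %*% b_exp),
                                     Sigma = ld / n_eff_exp))
    bhat_out <- unname(MASS::mvrnorm(1, mu = drop(ld %*% b_out),
                                     Sigma = ld / n_eff_out))
    list(eaf = eaf, bhat_exp = bhat_exp, bhat_out = bhat_out,
         b_out = b_out)
  })
  se_exp <- rep(1 / sqrt(n_eff_exp), m)
  se_out <- rep(1 / sqrt(n_eff_out), m)
  bhat_exp <- sim$bhat_exp
  bhat_out <- sim$bhat_out
  if (scale == "per_allele") {
    conv <- 1 / sqrt(2 * sim$eaf * (1 - sim$eaf))
    bhat_exp <- bhat_exp * conv; se_exp <- se_exp * conv
    bhat_out <- bhat_out * conv; se_out <- se_out * conv
  }
  truth$causal_exp <- cz$causal_exp
  truth$causal_out <- cz$causal_out
  truth$b_exp_true <- b_exp
  truth$b_out_true <- sim$b_out
  exposure <- list(variant_ids = ids, chrom = rep("1", m), pos = pos,
                   effect_allele = rep("A", m), other_allele = rep("G", m),
                   eaf = sim$eaf, beta = bhat_exp, se = se_exp,
                   pval = clamp_pval(2 * pnorm(-abs(bhat_exp / se_exp))),
                   n = n_exp, trait_type = "quantitative")
  outcome <- list(variant_ids = ids, chrom = rep("1", m), pos = pos,
                  effect_allele = rep("A", m), other_allele = rep("G", m),
                  eaf = sim$eaf, beta = bhat_out, se = se_out,
                  pval = clamp_pval(2 * pnorm(-abs(bhat_out / se_out))),
                  n = n_out, trait_type = "case_control",
                  case_fraction = case_fraction)
  list(ld = ld, exposure = exposure, outcome = outcome, truth = truth)
}

#' Locus dataset as a variant-record data frame
#'
#' Converts a [simulate_locus()] trait component to the record schema
#' consumed by the instrument-selection and harmonization functions.
#'
#' @param trait `exposure` or `outcome` component of a simulated locus.
#' @return Data frame on the [read_sumstats()] record schema.
#' @export
locus_records <- function(trait) {
  data.frame(variant_id = trait$variant_ids, chrom = trait$chrom,
             pos = trait$pos, effect_allele = trait$effect_allele,
             other_allele = trait$other_allele, eaf = trait$eaf,
             beta = trait$beta, se = trait$se, pval = trait$pval,
             n = trait$n, trait_type = trait$trait_type,
             stringsAsFactors = FALSE)
}

#' Harmonized pairs for a simulated locus
#'
#' @param study Output of [simulate_locus()].
#' @return Harmonized pairs data frame (all aligned by construction).
#' @export
locus_pairs <- function(study) {
  harmonized_kept(harmonize(locus_records(study$exposure),
                            locus_records(study$outcome)))
}

#' Simulate an independent-instrument protein study
#'
#' Generates `j_instruments` independent (post-clumping abstraction)
#' cis instruments for one protein. Exposure effects are sized so each
#' per-variant F falls in `f_band` (magnitude uniform on the implied z
#' range, random sign); each instrument's outcome effect is
#' `gamma * beta_exp` plus a direct effect drawn from
#' `N(pleiotropy_mean, pleiotropy_sd)`, and a configured fraction of
#' instruments receive an additional large direct effect (the ratio
#' displaced by 10 outcome SEs), with their ids recorded in the truth.
#' Betas are on the per-allele scale with EAF uniform on (0.05, 0.95).
#'
#' @param j_instruments Number of instruments (>= 1).
#' @param gamma True causal effect (log-OR per SD protein).
#' @param pleiotropy_mean,pleiotropy_sd Direct-effect distribution
#'   (per-allele log-odds).
#' @param outlier_fraction Fraction of instruments made outliers.
#' @param n_exp,n_out,case_fraction Cohort sizes as in [simulate_locus()].
#' @param f_band Per-variant F-statistic target band (default
#'   c(100, 1000), typical of strong cis-pQTLs).
#' @param seed RNG seed.
#' @return List with `pairs` (harmonized-pair schema, plus `f_stat`) and
#'   `truth` (gamma, pleiotropy parameters, `outlier_ids`, seed).
#' @export
simulate_mr_protein <- function(j_instruments, gamma = 0,
                                pleiotropy_mean = 0, pleiotropy_sd = 0,
                                outlier_fraction = 0,
                                n_exp = .DEFAULT_N_EXP,
                                n_out = .DEFAULT_N_OUT,
                                case_fraction = .DEFAULT_CASE_FRACTION,
                                f_band = c(100, 1000), seed = NULL) {
  if (j_instruments < 1) stop("j_instruments must be >= 1", call. = FALSE)
  j <- j_instruments
  n_eff_out <- n_out * case_fraction * (1 - case_fraction)
  sim <- with_seed(seed, {
    eaf <- runif(j, 0.05, 0.95)
    z_true <- sqrt(runif(j, f_band[1], f_band[2]))
    # instruments are emitted oriented to the protein-increasing allele
    # (the usual post-harmonization convention); directional pleiotropy is
    # only meaningful relative to that orientation
    b_std <- z_true / sqrt(n_exp)                # standardized scale
    conv <- 1 / sqrt(2 * eaf * (1 - eaf))        # to per-allele
    beta_exp_true <- b_std * conv
    se_exp <- conv / sqrt(n_exp)
    se_out <- conv / sqrt(n_eff_out)
    direct <- rnorm(j, pleiotropy_mean, pleiotropy_sd)
    n_outlier <- round(outlier_fraction * j)
    outlier_idx <- if (n_outlier > 0) sample.int(j, n_outlier) else integer(0)
    outlier_shift <- rep(0, j)
    if (n_outlier > 0)
      outlier_shift[outlier_idx] <-
        10 * se_out[outlier_idx] * sample(c(-1, 1), n_outlier, replace = TRUE)
    beta_out_true <- gamma * beta_exp_true + direct + outlier_shift
    beta_exp <- rnorm(j, beta_exp_true, se_exp)
    beta_out <- rnorm(j, beta_out_true, se_out)
    list(eaf = eaf, beta_exp = beta_exp, se_exp = se_exp,
         beta_out = beta_out, se_out = se_out, outlier_idx = outlier_idx)
  })
  ids <- sprintf("iv_%02d", seq_len(j))
  pairs <- data.frame(
    variant_id = ids, effect_allele = "A", other_allele = "G",
    eaf_exp = sim$eaf, beta_exp = sim$beta_exp, se_exp = sim$se_exp,
    eaf_out = sim$eaf, beta_out = sim$beta_out, se_out = sim$se_out,
    n_exp = n_exp, n_out = n_out, flag = "aligned",
    stringsAsFactors = FALSE)
  pairs$f_stat <- f_statistic(variance_explained(pairs$eaf_exp,
                                                 pairs$beta_exp),
                              pairs$n_exp, 1)
  list(pairs = pairs,
       truth = list(gamma = gamma, pleiotropy_mean = pleiotropy_mean,
                    pleiotropy_sd = pleiotropy_sd,
                    outlier_ids = ids[sim$outlier_idx], seed = seed))
}

#' Simulate a multi-protein study
#'
#' Independent protein studies, a stated fraction causal with effect
#' `gamma`, for pipeline-level power and family-wise-error evaluation.
#' With `n_proteins = 1` this degenerates to [simulate_mr_protein()].
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param fraction_causal Fraction with a nonzero causal effect.
#' @param gamma Causal effect for causal proteins.
#' @param j_instruments Instruments per protein (recycled).
#' @param seed RNG seed; per-protein sub-seeds are derived from it.
#' @param ... Passed through to [simulate_mr_protein()].
#' @return List with `studies` (named list of protein studies) and
#'   `truth` (data frame: `protein_id`, `gamma`, `causal`).
#' @export
simulate_proteome <- function(n_proteins, fraction_causal = 0.1,
                              gamma = 0.3, j_instruments = 5, seed = 1L,
                              ...) {
  if (n_proteins < 1) stop("n_proteins must be >= 1", call. = FALSE)
  n_causal <- round(fraction_causal * n_proteins)
  causal <- with_seed(seed, {
    flags <- rep(FALSE, n_proteins)
    if (n_causal > 0) flags[sample.int(n_proteins, n_causal)] <- TRUE
    flags
  })
  j_vec <- rep_len(j_instruments, n_proteins)
  ids <- sprintf("protein_%03d", seq_len(n_proteins))
  studies <- lapply(seq_len(n_proteins), function(i) {
    # derive sub-seeds in double precision: integer multiply overflows
    sub_seed <- as.integer((as.numeric(seed) * 1009 + i) %% 2147483647)
    simulate_mr_protein(j_vec[i], gamma = if (causal[i]) gamma else 0,
                        seed = sub_seed, ...)
  })
  names(studies) <- ids
  list(studies = studies,
       truth = data.frame(protein_id = ids,
                          gamma = ifelse(causal, gamma, 0),
                          causal = causal, stringsAsFactors = FALSE))
}

#' Named scenario presets
#'
#' Fixture presets covering the architectures and failure modes the
#' pipeline must handle: `H0` through `H4` are locus scenarios for
#' colocalization and SMR/HEIDI; `pleiotropy_directional`, `outliers` and
#' `weak_instruments` parameterize [simulate_mr_protein()].
#'
#' @param name Preset name.
#' @return For locus presets, a [scenario_truth()]; for protein presets, a
#'   named list of [simulate_mr_protein()] arguments.
#' @export
scenario_preset <- function(name = c("H0", "H1", "H2", "H3", "H4",
                                     "pleiotropy_directional", "outliers",
                                     "weak_instruments")) {
  name <- match.arg(name)
  switch(name,
         H0 = scenario_truth("H0_null"),
         H1 = scenario_truth("H1_protein_only"),
         H2 = scenario_truth("H2_disease_only"),
         H3 = scenario_truth("H3_linkage"),
         H4 = scenario_truth("H4_shared"),
         pleiotropy_directional = list(j_instruments = 20, gamma = 0,
                                       pleiotropy_mean = 0.05,
                                       pleiotropy_sd = 0.01),
         outliers = list(j_instruments = 20, gamma = 0.3,
                         outlier_fraction = 0.1),
         weak_instruments = list(j_instruments = 10, gamma = 0.3,
                                 f_band = c(4, 15)))
}
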