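# Orchestration: per-protein estimator suite + adjudication, discovery and
# replication Bonferroni logic, colocalization and SMR/HEIDI triangulation,
# Table-1-style reporting and the run manifest.

#' Default pipeline configuration
#'
#' All thresholds default to the working values of the analysis:
#' genome-wide significance p < 5e-8, clumping r-squared < 0.1 within
#' 1000 kb, cis window 1 Mb, instrument F > 10, test level alpha = 0.05,
#' colocalization PP4 > 0.80, HEIDI p > 0.05, coloc priors
#' (1e-4, 1e-4, 1e-5).
#'
#' @param ... Overrides of any default element.
#' @return Named list.
#' @export
run_config <- function(...) {
  cfg <- list(p_threshold = 5e-8, r2_threshold = 0.1, window_kb = 1000,
              cis_window_bp = 1e6, f_min = 10, f_formula = "standard",
              alpha = 0.05, pp4_threshold = 0.80, heidi_alpha = 0.05,
              coloc_priors = c(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5),
              ivw_default = "fixed", replication_mode = "any",
              require_direction = TRUE, n_boot = 1000,
              n_presso_sim = 1000, seed = 1L)
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  cfg
}

#' Select and harmonize instruments from full summary statistics
#'
#' The instrument-selection path for one protein: restrict exposure
#' records to the cis window of the encoding gene, apply the genome-wide
#' significance threshold, greedily clump on LD, harmonize against the
#' outcome, and drop weak instruments (per-variant F).
#'
#' @param exposure,outcome Variant record data frames.
#' @param gene Gene annotation (`gene_id`, `chrom`, `start`, `end`).
#' @param ld Signed correlation matrix covering the exposure variants.
#' @param config [run_config()] list.
#' @return List with `pairs` (qualified harmonized pairs), `n_cis`,
#'   `n_significant`, `n_clumped`, `n_harmonized`, `n_qualified`.
#' @export
prepare_instruments <- function(exposure, outcome, gene, ld,
                                config = run_config()) {
  cis <- select_cis(exposure, gene, config$cis_window_bp)
  sig <- filter_pvalue(cis, config$p_threshold)
  clumped <- if (nrow(sig)) ld_clump(sig, ld, config$r2_threshold,
                                     config$window_kb) else sig
  pairs <- if (nrow(clumped))
    harmonized_kept(harmonize(clumped, outcome))
  else data.frame()
  qualified <- if (nrow(pairs)) {
    stats <- instrument_stats(pairs, config$f_formula)
    pairs$f_stat <- stats$f_stat
    filter_weak(pairs, config$f_min)
  } else pairs
  list(pairs = qualified, n_cis = nrow(cis), n_significant = nrow(sig),
       n_clumped = nrow(clumped),
       n_harmonized = if (is.null(nrow(pairs))) 0L else nrow(pairs),
       n_qualified = if (is.null(nrow(qualified))) 0L else nrow(qualified))
}

#' Estimator suite, diagnostics and adjudication for one protein
#'
#' Runs every estimator applicable at the instrument count, the
#' diagnostics (Cochran's Q, Egger intercept, MR-PRESSO global), flag
#' detection, and the method-selection tree.
#'
#' @param pairs Qualified harmonized pairs.
#' @param config [run_config()] list (`n_boot`, `n_presso_sim`, `alpha`,
#'   `seed` are used).
#' @param include_modes Also compute the simple- and weighted-mode
#'   sensitivity estimators (default FALSE; they are not candidates in
#'   the adjudication tree).
#' @return List with `status`, `n_snp`, `estimates` (named list),
#'   `diagnostics`, `flags`, `adjudicated`.
#' @export
analyze_protein <- function(pairs, config = run_config(),
                            include_modes = FALSE) {
  j <- nrow(pairs)
  if (j == 0L)
    return(list(status = "no qualified instrument", n_snp = 0L,
                estimates = list(), diagnostics = NULL, flags = NULL,
                adjudicated = NULL))
  seed <- config$seed
  estimates <- list()
  if (j == 1L) {
    estimates$wald_ratio <- wald_ratio(pairs)
    diagnostics <- list(q_stat = NA_real_, q_df = NA_integer_,
                        q_pval = NA_real_, egger_intercept = NA_real_,
                        egger_intercept_se = NA_real_,
                        egger_intercept_pval = NA_real_,
                        presso_global_pval = NA_real_,
                        presso_outliers = character(0))
  } else {
    estimates$ivw_fe <- mr_ivw(pairs, "fixed")
    estimates$ivw_mre <- mr_ivw(pairs, "multiplicative_random")
    eg <- mr_egger(pairs)
    estimates$egger <- eg$estimate
    estimates$weighted_median <-
      mr_weighted_median(pairs, n_boot = config$n_boot, seed = seed)
    pr <- mr_presso(pairs, n_sim = config$n_presso_sim, seed = seed + 1L)
    estimates$presso_corrected <- pr$corrected
    if (include_modes) {
      estimates$simple_mode <- mr_mode(pairs, "simple",
                                       n_boot = config$n_boot,
                                       seed = seed + 2L)
      estimates$weighted_mode <- mr_mode(pairs, "weighted",
                                         n_boot = config$n_boot,
                                         seed = seed + 3L)
    }
    q <- estimates$ivw_fe$extras
    diagnostics <- list(q_stat = q$q_stat, q_df = q$q_df,
                        q_pval = q$q_pval,
                        egger_intercept = eg$intercept,
                        egger_intercept_se = eg$intercept_se,
                        egger_intercept_pval = eg$intercept_pval,
                        presso_global_pval = pr$global_pval,
                        presso_outliers = pr$outliers)
  }
  flags <- detect_flags(diagnostics, config$alpha)
  adjudicated <- choose_primary(estimates, flags, j)
  list(status = if (adjudicated$inconclusive) "inconclusive" else "ok",
       n_snp = j, estimates = estimates, diagnostics = diagnostics,
       flags = flags, adjudicated = adjudicated)
}

# Qualified pairs from a study entry: either a simulate_mr_protein()
# result, or a bare harmonized-pairs data frame.
study_pairs <- function(study, config) {
  pairs <- if (is.data.frame(study)) study else study$pairs
  if (!nrow(pairs)) return(pairs)
  if (is.null(pairs$f_stat)) {
    stats <- instrument_stats(pairs, config$f_formula)
    pairs$f_stat <- stats$f_stat
  }
  filter_weak(pairs, config$f_min)
}

#' Discovery-stage proteome-wide MR
#'
#' For each protein: weak-instrument filtering, the estimator suite,
#' diagnostics-driven adjudication, then Bonferroni correction with m
#' equal to the number of proteins with a valid primary estimate.
#'
#' @param studies Named list of protein studies (each a
#'   [simulate_mr_protein()] result or a harmonized-pairs data frame).
#' @param config [run_config()] list.
#' @return List with `results` (one row per protein: method, beta, se,
#'   OR and CI, p-value, n_snp, flags, `significant`), `m` (Bonferroni
#'   denominator), `details` (per-protein [analyze_protein()] output),
#'   `dropped` (proteins with no qualified instrument, with reasons).
#' @export
run_discovery <- function(studies, config = run_config()) {
  if (is.null(names(studies)) || any(!nzchar(names(studies))))
    stop("studies must be a named list", call. = FALSE)
  details <- lapply(studies, function(s)
    analyze_protein(study_pairs(s, config), config))
  valid <- vapply(details, function(d) d$status == "ok", logical(1))
  m <- sum(valid)
  if (m == 0L)
    stop("no protein has a valid MR estimate; reasons: ",
         paste(unique(vapply(details, `[[`, character(1), "status")),
               collapse = ", "), call. = FALSE)
  rows <- lapply(names(studies), function(id) {
    d <- details[[id]]
    if (d$status != "ok")
      return(data.frame(protein_id = id, method = NA_character_,
                        beta = NA_real_, se = NA_real_, or = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        pval = NA_real_, n_snp = d$n_snp,
                        heterogeneity = NA, pleiotropy = NA,
                        status = d$status, stringsAsFactors = FALSE))
    est <- d$adjudicated$primary_estimate
    data.frame(protein_id = id, method = d$adjudicated$primary_method,
               beta = est$beta, se = est$se, or = exp(est$beta),
               ci_low = est$ci_low, ci_high = est$ci_high,
               pval = est$pval, n_snp = d$n_snp,
               heterogeneity = d$adjudicated$heterogeneity_detected,
               pleiotropy = d$adjudicated$pleiotropy_detected,
               status = "ok", stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  results$significant <- unname(bonferroni_flag(
    setNames(results$pval, results$protein_id), m, config$alpha))
  dropped <- results$protein_id[results$status != "ok"]
  list(results = results, m = m, details = details, dropped = dropped)
}

#' Full triangulation run
#'
#' Discovery MR, replication in additional cohort combinations,
#' prioritization by replication consistency, fixed-effect meta-analysis
#' of discovery and replication estimates, Bayesian colocalization and
#' SMR/HEIDI at the protein loci, assembled into a Table-1-style report
#' (one row per discovery-significant protein) plus a run manifest.
#' Stages that are not applicable propagate as NA, never silent blanks.
#'
#' @param discovery Named list of protein studies for the discovery
#'   combination.
#' @param replications Named list of replication combinations, each a
#'   named list of protein studies (proteins absent from a combination
#'   simply have no entry).
#' @param loci Named list (by protein) of [simulate_locus()]-style
#'   objects (`exposure`, `outcome`, `ld`) for colocalization and
#'   SMR/HEIDI; proteins without a locus get NA in those columns.
#' @param config [run_config()] list.
#' @param out_dir Optional directory; when given, writes
#'   `results_table.tsv`, `diagnostics.tsv` and `manifest.json`.
#' @return List with `table` (Table-1-style data frame), `discovery`,
#'   `replications`, `manifest`.
#' @export
run_full <- function(discovery, replications = list(), loci = list(),
                     config = run_config(), out_dir = NULL) {
  disc <- run_discovery(discovery, config)
  reps <- lapply(replications, run_discovery, config = config)
  sig_ids <- disc$results$protein_id[disc$results$significant %in% TRUE]
  m_smr <- length(sig_ids)

  rows <- lapply(sig_ids, function(id) {
    drow <- disc$results[disc$results$protein_id == id, ]
    rep_entries <- lapply(reps, function(r) {
      rr <- r$results[r$results$protein_id == id, ]
      if (!nrow(rr) || rr$status != "ok") return(NULL)
      list(significant = isTRUE(rr$significant), beta = rr$beta,
           pval = rr$pval, se = rr$se, n_snp = rr$n_snp)
    })
    prio <- replication_consistency(
      list(significant = TRUE, beta = drow$beta), rep_entries,
      require_direction = config$require_direction,
      mode = config$replication_mode)
    present <- Filter(Negate(is.null), rep_entries)
    p_rep <- if (length(present))
      min(vapply(present, `[[`, numeric(1), "pval")) else NA_real_
    meta <- {
      ests <- c(list(mr_estimate("discovery", drow$beta, drow$se,
                                 n_snp = drow$n_snp)),
                lapply(present, function(r)
                  mr_estimate("replication", r$beta, r$se,
                              n_snp = r$n_snp)))
      if (length(ests) >= 2L) meta_fixed(ests) else ests[[1L]]
    }
    locus <- loci[[id]]
    if (!is.null(locus)) {
      cp <- config$coloc_priors
      coloc <- coloc_abf(locus$exposure, locus$outcome,
                         p1 = cp[["p1"]], p2 = cp[["p2"]],
                         p12 = cp[["p12"]])
      pairs <- locus_pairs(locus)
      smr <- smr_analysis(pairs, locus$ld)
      smr_cls <- classify_smr(smr$p_smr, max(m_smr, 1L), smr$p_heidi,
                              config$heidi_alpha)
      pp4 <- coloc$pp4
      colocalized <- classify_coloc(coloc, config$pp4_threshold)
    } else {
      pp4 <- NA_real_; colocalized <- NA
      smr <- list(b_smr = NA_real_, p_smr = NA_real_, p_heidi = NA_real_)
      smr_cls <- list(passed = NA)
    }
    data.frame(protein_id = id, method = drow$method,
               or = exp(drow$beta), or_ci_low = exp(drow$ci_low),
               or_ci_high = exp(drow$ci_high), p_discovery = drow$pval,
               p_replication = p_rep, pp_h4 = pp4,
               colocalized = colocalized, smr_beta = smr$b_smr,
               smr_p = smr$p_smr, heidi_p = smr$p_heidi,
               smr_passed = smr_cls$passed,
               meta_beta = meta$beta, meta_se = meta$se,
               prioritized = prio$prioritized, reason = prio$reason,
               stringsAsFactors = FALSE)
  })
  table <- if (length(rows)) do.call(rbind, rows) else data.frame()

  manifest <- list(
    package_version = as.character(utils::packageVersion("targetMR")),
    config = config,
    seed = config$seed,
    m_discovery = disc$m,
    m_replication = lapply(reps, `[[`, "m"),
    m_smr = m_smr,
    proteins = lapply(names(discovery), function(id) {
      d <- disc$details[[id]]
      list(protein_id = id, status = d$status, n_snp = d$n_snp,
           flags = if (!is.null(d$flags)) as.list(d$flags) else NULL,
           chosen = if (!is.null(d$adjudicated))
             d$adjudicated$primary_method else NA,
           candidates = if (!is.null(d$adjudicated))
             d$adjudicated$candidate_methods_considered else NULL,
           excluded = if (!is.null(d$adjudicated))
             d$adjudicated$excluded_methods else NULL)
    }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(table, file.path(out_dir, "results_table.tsv"))
    diag_rows <- do.call(rbind, lapply(names(discovery), function(id) {
      d <- disc$details[[id]]
      dg <- d$diagnostics
      data.frame(protein_id = id,
                 q_pval = if (is.null(dg)) NA_real_ else dg$q_pval,
                 egger_intercept_pval = if (is.null(dg)) NA_real_
                   else dg$egger_intercept_pval,
                 presso_global_pval = if (is.null(dg)) NA_real_
                   else dg$presso_global_pval,
                 stringsAsFactors = FALSE)
    }))
    write_tsv(diag_rows, file.path(out_dir, "diagnostics.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  list(table = table, discovery = disc, replications = reps,
       manifest = manifest)
}
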