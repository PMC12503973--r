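#!/usr/bin/env Rscript
# Step 3 — replication MR and cross-cohort meta-analysis.
#
# Re-runs the MR pipeline in each of the three replication cohort
# combinations (each with its own Bonferroni denominator), checks
# replication consistency (at least one significant replication with the
# discovery's effect direction) for every discovery-significant protein,
# and pools discovery + replication estimates by fixed-effect
# inverse-variance meta-analysis. Writes results/replication.tsv.

suppressMessages(library(targetMR))

cfg <- run_config(seed = 42L, n_boot = 1000, n_presso_sim = 1000)
read_studies <- function(path) {
  long <- read.delim(path)
  split(long[, setdiff(names(long), "protein_id")], long$protein_id)
}
disc <- run_discovery(read_studies("results/sim/instruments_discovery.tsv"),
                      cfg)
combos <- c("rep_a", "rep_b", "rep_c")
reps <- lapply(combos, function(cb)
  run_discovery(read_studies(
    sprintf("results/sim/instruments_%s.tsv", cb)), cfg))
names(reps) <- combos
for (cb in combos)
  message(sprintf("replication %-15s m = %d", cb, reps[[cb]]$m))

sig <- disc$results[disc$results$significant %in% TRUE, ]
rows <- lapply(seq_len(nrow(sig)), function(i) {
  id <- sig$protein_id[i]
  rep_entries <- lapply(reps, function(r) {
    rr <- r$results[r$results$protein_id == id, ]
    if (!nrow(rr) || rr$status != "ok") return(NULL)
    list(significant = isTRUE(rr$significant), beta = rr$beta,
         se = rr$se, pval = rr$pval, n_snp = rr$n_snp)
  })
  prio <- replication_consistency(
    list(significant = TRUE, beta = sig$beta[i]), rep_entries,
    require_direction = cfg$require_direction)
  present <- Filter(Negate(is.null), rep_entries)
  ests <- c(list(mr_estimate("discovery", sig$beta[i], sig$se[i],
                             n_snp = sig$n_snp[i])),
            lapply(present, function(r)
              mr_estimate("replication", r$beta, r$se, n_snp = r$n_snp)))
  meta <- if (length(ests) >= 2) meta_fixed(ests) else ests[[1]]
  data.frame(protein_id = id, beta_discovery = sig$beta[i],
             p_discovery = sig$pval[i],
             n_replications = length(present),
             p_replication_best = if (length(present))
               min(vapply(present, `[[`, numeric(1), "pval")) else NA_real_,
             meta_or = exp(meta$beta),
             meta_ci_low = exp(meta$ci_low),
             meta_ci_high = exp(meta$ci_high),
             prioritized = prio$prioritized, reason = prio$reason)
})
out <- do.call(rbind, rows)
write_tsv(out, "results/replication.tsv")
message(sprintf("%d of %d discovery-significant proteins prioritized: %s",
                sum(out$prioritized), nrow(out),
                paste(out$protein_id[out$prioritized], collapse = ", ")))
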