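#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study.
#
# Builds a 60-protein synthetic proteome with 6 causal proteins
# (log-OR 0.4 per SD of protein) at the discovery cohort scale
# (pQTL n = 54,219; GWAS n = 306,075 with 7589 cases), three replication
# cohort combinations at their own scales with partial protein coverage,
# and per-protein locus data (50 variants under AR(1) LD) for
# colocalization and SMR/HEIDI at the causal proteins — one of them a
# deliberate linkage (distinct-causal-variant) locus so the HEIDI test
# has something to catch. Everything is written as TSV under
# results/sim/.

suppressMessages(library(targetMR))

seed <- 42L
out_dir <- "results/sim"
dir.create(file.path(out_dir, "loci"), showWarnings = FALSE,
           recursive = TRUE)

message("simulating discovery proteome (60 proteins, 6 causal) ...")
proteome <- simulate_proteome(60, fraction_causal = 0.1, gamma = 0.4,
                              j_instruments = 5, seed = seed)
write_tsv(proteome$truth, file.path(out_dir, "truth.tsv"))

studies_tsv <- function(studies) {
  do.call(rbind, lapply(names(studies), function(id) {
    df <- studies[[id]]$pairs
    cbind(protein_id = id, df)
  }))
}
write_tsv(studies_tsv(proteome$studies),
          file.path(out_dir, "instruments_discovery.tsv"))

# replication combinations: same causal truth, independent sampling noise,
# cohort scales of the replication datasets, ~75% protein coverage each
rep_scales <- list(
  rep_a = list(n_exp = 35559, n_out = 306075,
               case_fraction = 7589 / 306075),
  rep_b = list(n_exp = 35559, n_out = 439724,
               case_fraction = 27144 / 439724),
  rep_c = list(n_exp = 54219, n_out = 439724,
               case_fraction = 27144 / 439724))
for (k in seq_along(rep_scales)) {
  combo <- names(rep_scales)[k]
  sc <- rep_scales[[k]]
  set.seed(seed + k)
  covered <- sort(sample.int(60, 45))
  studies <- lapply(covered, function(i)
    simulate_mr_protein(5, gamma = proteome$truth$gamma[i],
                        n_exp = sc$n_exp, n_out = sc$n_out,
                        case_fraction = sc$case_fraction,
                        seed = seed * 100L + k * 1000L + i))
  names(studies) <- proteome$truth$protein_id[covered]
  write_tsv(studies_tsv(studies),
            file.path(out_dir, sprintf("instruments_%s.tsv", combo)))
  message(sprintf("  replication %-15s %d proteins", combo,
                  length(studies)))
}

# locus data for the causal proteins: shared-variant architecture except
# one linkage locus
causal_ids <- proteome$truth$protein_id[proteome$truth$causal]
message("simulating loci for causal proteins: ",
        paste(causal_ids, collapse = ", "))
for (i in seq_along(causal_ids)) {
  id <- causal_ids[i]
  truth <- if (i == length(causal_ids))
    scenario_truth("H3_linkage", causal_exp = 17, causal_out = 20,
                   z_exp = 12, z_out = 10)
  else scenario_truth("H4_shared", gamma = NULL, z_exp = 12, z_out = 9)
  st <- simulate_locus(truth, seed = seed * 10L + i)
  write_tsv(locus_records(st$exposure),
            file.path(out_dir, "loci", paste0(id, "_exposure.tsv")))
  write_tsv(locus_records(st$outcome),
            file.path(out_dir, "loci", paste0(id, "_outcome.tsv")))
  write_ld_matrix(st$ld,
                  file.path(out_dir, "loci", paste0(id, "_ld.tsv")))
  if (truth$architecture == "H3_linkage")
    message("  ", id, ": linkage locus (distinct causal variants)")
}
message("done; outputs under ", out_dir)
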