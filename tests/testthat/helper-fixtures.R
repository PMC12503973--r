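# Shared fixture builders. Everything is generated in code at test time.

# Minimal harmonized-pairs data frame from ratio components.
make_pairs <- function(beta_exp, se_exp, beta_out, se_out,
                       eaf = NULL, n_exp = 50000, n_out = 300000) {
  j <- length(beta_exp)
  data.frame(variant_id = sprintf("iv_%02d", seq_len(j)),
             effect_allele = "A", other_allele = "G",
             eaf_exp = if (is.null(eaf)) rep(0.3, j) else eaf,
             beta_exp = beta_exp, se_exp = rep_len(se_exp, j),
             eaf_out = if (is.null(eaf)) rep(0.3, j) else eaf,
             beta_out = beta_out, se_out = rep_len(se_out, j),
             n_exp = n_exp, n_out = n_out, flag = "aligned",
             stringsAsFactors = FALSE)
}

# The two-instrument worked example: ratio estimates 0.5 (weight 100)
# and 1.0 (weight 25).
example_pairs_ivw <- function() {
  make_pairs(beta_exp = c(0.1, 0.2), se_exp = 0.01,
             beta_out = c(0.05, 0.2), se_out = c(0.01, 0.04))
}

# Variant records on the read_sumstats() schema.
make_records <- function(n, chrom = "1", pos = NULL, pval = NULL,
                         eaf = NULL, beta = NULL, se = 0.02,
                         n_samp = 50000, ea = "A", oa = "G",
                         ids = NULL) {
  data.frame(variant_id = if (is.null(ids)) sprintf("rs%04d", seq_len(n))
             else ids,
             chrom = rep_len(chrom, n),
             pos = if (is.null(pos)) seq(1e6, by = 5e3, length.out = n)
             else pos,
             effect_allele = rep_len(ea, n), other_allele = rep_len(oa, n),
             eaf = if (is.null(eaf)) rep(0.3, n) else eaf,
             beta = if (is.null(beta)) rep(0.1, n) else beta,
             se = rep_len(se, n),
             pval = if (is.null(pval)) rep(1e-10, n) else pval,
             n = rep_len(n_samp, n), stringsAsFactors = FALSE)
}

# Write records to a temporary TSV and return the path.
write_sumstats_tsv <- function(records, path = tempfile(fileext = ".tsv")) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
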