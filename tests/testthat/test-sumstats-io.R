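test_that("well-formed rows are read back unchanged and invalid rows are rejected with reasons", {
  rec <- make_records(3, pval = c(1e-10, 1e-9, 1e-8))
  path <- write_sumstats_tsv(rec)
  out <- read_sumstats(path)
  expect_equal(nrow(out$records), 3L)
  expect_equal(out$n_rejected, 0L)
  expect_equal(out$records$beta, rec$beta)
  expect_equal(out$records$variant_id, rec$variant_id)

  bad <- make_records(4)
  bad$se[2] <- 0
  bad$eaf[3] <- 1.0
  bad$beta[4] <- NA
  out <- read_sumstats(write_sumstats_tsv(bad))
  expect_equal(nrow(out$records), 1L)
  expect_equal(out$n_rejected, 3L)
  expect_setequal(out$rejections$reason,
                  c("nonpositive SE", "EAF out of (0,1)",
                    "unparseable numeric"))
  # row order of retained records is preserved
  expect_equal(out$records$variant_id, bad$variant_id[1])
})

test_that("comma-delimited input and custom dialects are handled; missing columns error", {
  rec <- make_records(2)
  names(rec)[names(rec) == "beta"] <- "Effect"
  names(rec)[names(rec) == "pval"] <- "P"
  path <- tempfile(fileext = ".csv")
  write.table(rec, path, sep = ",", quote = FALSE, row.names = FALSE)
  dia <- default_dialect()
  dia$beta <- "Effect"; dia$pval <- "P"
  out <- read_sumstats(path, dialect = dia)
  expect_equal(nrow(out$records), 2L)
  expect_error(read_sumstats(path), "missing mandatory column")
})

test_that("indels and non-ACGT alleles are rejected rows, not errors", {
  rec <- make_records(3)
  rec$effect_allele[1] <- "AT"
  rec$other_allele[2] <- "N"
  out <- read_sumstats(write_sumstats_tsv(rec))
  expect_equal(nrow(out$records), 1L)
  expect_setequal(out$rejections$reason,
                  c("indel alleles not supported", "allele not in A/C/G/T"))
})

test_that("palindrome detection covers both orders and rejects bad alleles", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("T", "A"))
  expect_true(is_palindromic("C", "G"))
  expect_true(is_palindromic("G", "C"))
  expect_false(is_palindromic("A", "G"))
  expect_false(is_palindromic("C", "T"))
  expect_error(is_palindromic("A", "N"), "A/C/G/T")
})

test_that("harmonization flips swapped alleles, drops ambiguous palindromes, keeps identical alleles", {
  exp <- make_records(3, ids = c("v1", "v2", "v3"),
                      ea = c("A", "A", "C"), oa = c("G", "T", "T"),
                      eaf = c(0.20, 0.50, 0.30),
                      beta = c(0.10, 0.10, 0.10))
  out <- make_records(3, ids = c("v1", "v2", "v3"),
                      ea = c("G", "A", "C"), oa = c("A", "T", "T"),
                      eaf = c(0.80, 0.50, 0.30),
                      beta = c(-0.05, 0.02, 0.07))
  h <- harmonize(exp, out)
  expect_equal(h$flag, c("flipped", "dropped_palindromic", "aligned"))
  expect_equal(h$beta_out[1], 0.05)
  expect_equal(h$eaf_out[1], 0.20)
  expect_equal(h$beta_out[3], 0.07)
  # palindromic but unambiguous frequencies align by frequency
  exp2 <- make_records(1, ids = "v9", ea = "A", oa = "T", eaf = 0.10)
  out2a <- make_records(1, ids = "v9", ea = "A", oa = "T", eaf = 0.12,
                        beta = 0.03)
  out2b <- make_records(1, ids = "v9", ea = "A", oa = "T", eaf = 0.88,
                        beta = 0.03)
  expect_equal(harmonize(exp2, out2a)$flag, "aligned")
  hb <- harmonize(exp2, out2b)
  expect_equal(hb$flag, "flipped")
  expect_equal(hb$beta_out, -0.03)
  expect_equal(hb$eaf_out, 0.12)
})

test_that("variants absent from the outcome or with incompatible alleles are dropped with reasons", {
  exp <- make_records(2, ids = c("v1", "v2"))
  out <- make_records(1, ids = "v1", ea = "A", oa = "C")
  h <- harmonize(exp, out)
  expect_equal(h$flag, c("dropped_mismatch", "dropped_mismatch"))
  expect_equal(h$reason, c("allele mismatch", "absent from outcome"))
  expect_equal(nrow(harmonized_kept(h)), 0L)
})

test_that("duplicate variant ids are an error naming the id", {
  exp <- make_records(2, ids = c("dup1", "dup1"))
  out <- make_records(2, ids = c("dup1", "v2"))
  expect_error(harmonize(exp, out), "dup1")
})

test_that("allele flip is involutive and preserves outcome effect magnitudes", {
  set.seed(42)
  comp <- c(A = "G", C = "T", G = "A", T = "C")  # swap partner (non-pal)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    ea <- sample(c("A", "C"), n, replace = TRUE)
    oa <- ifelse(ea == "A", "G", "T")            # never palindromic
    exp <- make_records(n, ea = ea, oa = oa,
                        eaf = runif(n, 0.05, 0.95),
                        beta = rnorm(n, 0, 0.1))
    swap <- runif(n) < 0.5
    out <- exp
    out$beta <- rnorm(n, 0, 0.05)
    out$effect_allele <- ifelse(swap, oa, ea)
    out$other_allele <- ifelse(swap, ea, oa)
    out$beta[swap] <- -out$beta[swap]
    out$eaf[swap] <- 1 - out$eaf[swap]
    h <- harmonize(exp, out)
    # every input variant appears exactly once with one flag
    expect_equal(h$variant_id, exp$variant_id)
    expect_true(all(h$flag %in% c("aligned", "flipped")))
    expect_equal(h$flag == "flipped", unname(swap))
    # the flip transform applied twice is the identity: harmonized
    # magnitudes match the pre-swap magnitudes
    expect_equal(sort(abs(h$beta_out)), sort(abs(out$beta)))
    # flipping an already-flipped record restores the original values
    out2 <- out
    out2$beta[swap] <- -out2$beta[swap]
    out2$eaf[swap] <- 1 - out2$eaf[swap]
    out2$effect_allele <- ea; out2$other_allele <- oa
    h2 <- harmonize(exp, out2)
    expect_equal(h$beta_out, h2$beta_out)
  }
})
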