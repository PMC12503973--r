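test_that("flag detection applies strict thresholds and either-or pleiotropy", {
  diag <- function(q, e, p) list(q_pval = q, egger_intercept_pval = e,
                                 presso_global_pval = p)
  expect_equal(unname(c(detect_flags(diag(0.01, 0.3, 0.4)))), c(TRUE, FALSE))
  expect_equal(unname(c(detect_flags(diag(0.2, 0.2, 0.01)))), c(FALSE, TRUE))
  expect_equal(unname(c(detect_flags(diag(0.2, 0.01, 0.2)))), c(FALSE, TRUE))
  # boundary: exactly alpha is not detected
  expect_equal(unname(c(detect_flags(diag(0.05, 0.05, 0.05)))),
               c(FALSE, FALSE))
  # missing diagnostics count as not detected and are recorded
  fl <- detect_flags(diag(0.01, NA, NA))
  expect_equal(unname(c(fl)), c(TRUE, FALSE))
  expect_setequal(attr(fl, "missing"), c("egger_intercept",
                                         "presso_global"))
})

test_that("the method-selection tree follows the flags and the largest-p rule", {
  est <- function(p) mr_estimate("x", 0.1, 0.05, pval = p, n_snp = 5)
  ests <- list(wald_ratio = est(0.5), ivw_fe = est(0.04),
               ivw_mre = est(0.07), weighted_median = est(0.03),
               egger = est(0.15), presso_corrected = est(0.2))
  flags <- function(h, p) c(heterogeneity = h, pleiotropy = p)
  expect_equal(choose_primary(ests, flags(FALSE, FALSE), 5)$primary_method,
               "ivw_fe")
  expect_equal(choose_primary(ests, flags(TRUE, FALSE), 5)$primary_method,
               "ivw_mre")     # 0.07 > 0.03
  expect_equal(choose_primary(ests, flags(FALSE, TRUE), 5)$primary_method,
               "presso_corrected")  # 0.2 > 0.15
  expect_equal(choose_primary(ests, flags(TRUE, TRUE), 5)$primary_method,
               "presso_corrected")  # largest of the four
  # single instrument forces the Wald ratio regardless of flags
  expect_equal(choose_primary(ests, flags(TRUE, TRUE), 1)$primary_method,
               "wald_ratio")
  # ties go to the earlier method in the listed order
  tie <- ests
  tie$weighted_median <- est(0.2); tie$ivw_mre <- est(0.01)
  tie$egger <- est(0.15); tie$presso_corrected <- est(0.2)
  expect_equal(choose_primary(tie, flags(TRUE, TRUE), 5)$primary_method,
               "weighted_median")
  # unavailable methods are excluded and recorded
  na_est <- ests
  na_est$egger <- targetMR:::mr_na("egger", 2, "df")
  sel <- choose_primary(na_est, flags(FALSE, TRUE), 5)
  expect_equal(sel$primary_method, "presso_corrected")
  expect_equal(sel$excluded_methods, "egger")
  # empty candidate set is inconclusive, not an error
  empty <- list()
  sel2 <- choose_primary(empty, flags(FALSE, FALSE), 5)
  expect_true(sel2$inconclusive)
})

test_that("adjudication is a pure function of its inputs", {
  est <- function(p) mr_estimate("x", 0.1, 0.05, pval = p, n_snp = 5)
  ests <- list(ivw_fe = est(0.04), ivw_mre = est(0.07),
               weighted_median = est(0.03), egger = est(0.15),
               presso_corrected = est(0.2))
  fl <- c(heterogeneity = TRUE, pleiotropy = FALSE)
  a <- choose_primary(ests, fl, 5)
  b <- choose_primary(ests, fl, 5)
  expect_identical(a, b)
})

test_that("Bonferroni flags use a strict threshold scaled by the test count", {
  expect_true(bonferroni_flag(c(x = 1.87e-7), m = 1763)[["x"]])
  expect_false(bonferroni_flag(c(x = 0.05 / 1763), m = 1763)[["x"]])
  expect_true(bonferroni_flag(c(x = 0.049), m = 1)[["x"]])
  expect_false(bonferroni_flag(c(x = NA_real_), m = 1)[["x"]])
  expect_error(bonferroni_flag(c(x = 0.01), m = 0), "m")
})

test_that("replication consistency requires discovery, one significant replication, and sign agreement", {
  disc <- list(significant = TRUE, beta = 0.5)
  sig_same <- list(significant = TRUE, beta = 0.4)
  sig_opp <- list(significant = TRUE, beta = -0.4)
  ns <- list(significant = FALSE, beta = 0.4)
  expect_true(replication_consistency(disc, list(sig_same, ns))$prioritized)
  out <- replication_consistency(disc, list(sig_opp))
  expect_false(out$prioritized)
  expect_match(out$reason, "direction")
  expect_false(replication_consistency(list(significant = FALSE,
                                            beta = 0.5),
                                       list(sig_same))$prioritized)
  none <- replication_consistency(disc, list(NULL, NULL))
  expect_false(none$prioritized)
  expect_match(none$reason, "no replication instruments")
  # "all" mode requires every present combination to be significant
  expect_false(replication_consistency(disc, list(sig_same, ns),
                                       mode = "all")$prioritized)
  expect_true(replication_consistency(disc, list(sig_same, NULL),
                                      mode = "all")$prioritized)
  # direction check can be disabled
  expect_true(replication_consistency(disc, list(sig_opp),
                                      require_direction = FALSE)$prioritized)
})

test_that("fixed-effect meta-analysis pools by inverse variance", {
  e1 <- mr_estimate("a", 0.5, 0.1, n_snp = 3)
  e2 <- mr_estimate("b", 0.7, 0.1, n_snp = 4)
  m <- meta_fixed(list(e1, e2))
  expect_equal(m$beta, 0.6, tolerance = 1e-12)
  expect_equal(m$se, sqrt(1 / 200), tolerance = 1e-12)
  # identical estimates: same beta, se / sqrt(2)
  m2 <- meta_fixed(list(e1, e1))
  expect_equal(m2$beta, 0.5)
  expect_equal(m2$se, 0.1 / sqrt(2))
  # single estimate passes through with a warning
  expect_warning(m3 <- meta_fixed(list(e1)), "single")
  expect_equal(m3$beta, 0.5)
  # pooling reduces variance below the best component
  set.seed(4)
  for (i in 1:10) {
    es <- lapply(1:3, function(j)
      mr_estimate("x", rnorm(1), runif(1, 0.05, 0.3), n_snp = 2))
    mm <- meta_fixed(es)
    expect_lte(mm$se, min(vapply(es, `[[`, numeric(1), "se")))
  }
})

test_that("meta pooling agrees with an independent fixed-effect oracle", {
  skip_if_not_installed("metafor")
  set.seed(8)
  b <- rnorm(4); se <- runif(4, 0.05, 0.2)
  es <- lapply(1:4, function(i) mr_estimate("x", b[i], se[i], n_snp = 2))
  fit <- metafor::rma(yi = b, sei = se, method = "FE")
  m <- meta_fixed(es)
  expect_equal(m$beta, as.numeric(fit$beta), tolerance = 1e-9)
  expect_equal(m$se, fit$se, tolerance = 1e-9)
})
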