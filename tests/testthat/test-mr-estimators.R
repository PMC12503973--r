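test_that("Wald ratio follows the delta rule and its sign symmetry", {
  w <- wald_ratio(make_pairs(0.1, 0.02, 0.05, 0.01))
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.1)
  z <- wald_ratio(make_pairs(0.1, 0.02, 0, 0.01))
  expect_equal(z$beta, 0)
  expect_equal(z$pval, 1)
  neg <- wald_ratio(make_pairs(-0.1, 0.02, 0.05, 0.01))
  expect_equal(neg$beta, -0.5)
  expect_equal(neg$se, 0.1)
  expect_error(wald_ratio(make_pairs(0, 0.02, 0.05, 0.01)), "nonzero")
})

test_that("IVW and Cochran's Q reproduce the two-instrument hand example exactly", {
  pairs <- example_pairs_ivw()
  fe <- mr_ivw(pairs, "fixed")
  expect_equal(fe$beta, 0.6, tolerance = 1e-12)
  expect_equal(fe$se, sqrt(1 / 125), tolerance = 1e-12)
  q <- cochran_q(pairs)
  expect_equal(q$q_stat, 5, tolerance = 1e-12)
  expect_equal(q$q_df, 1L)
  expect_equal(q$q_pval, pchisq(5, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  mre <- mr_ivw(pairs, "multiplicative_random")
  expect_equal(mre$se, sqrt(1 / 125) * sqrt(5), tolerance = 1e-12)
  # identical ratios: beta equals the common ratio, mre scale floored at 1
  same <- make_pairs(c(0.1, 0.2, 0.4), 0.01, c(0.05, 0.1, 0.2),
                     c(0.01, 0.02, 0.01))
  fe2 <- mr_ivw(same, "fixed")
  mre2 <- mr_ivw(same, "multiplicative_random")
  expect_equal(fe2$beta, 0.5)
  expect_equal(fe2$se, mre2$se)
  expect_equal(cochran_q(same)$q_pval, 1)
  expect_error(mr_ivw(pairs[1, ]), "wald_ratio")
})

test_that("IVW agrees with an independent inverse-variance pooling oracle", {
  skip_if_not_installed("metafor")
  set.seed(11)
  pairs <- make_pairs(rnorm(6, 0.2, 0.05), 0.01,
                      rnorm(6, 0.06, 0.03), runif(6, 0.01, 0.03))
  b <- pairs$beta_out / pairs$beta_exp
  se <- pairs$se_out / abs(pairs$beta_exp)
  fit <- metafor::rma(yi = b, sei = se, method = "FE")
  fe <- mr_ivw(pairs, "fixed")
  expect_equal(fe$beta, as.numeric(fit$beta), tolerance = 1e-9)
  expect_equal(fe$se, fit$se, tolerance = 1e-9)
  expect_equal(fe$extras$q_stat, fit$QE, tolerance = 1e-9)
})

test_that("Q by brute force matches on three equal-weight symmetric ratios", {
  pairs <- make_pairs(c(0.1, 0.1, 0.1), 0.01,
                      c(0.04, 0.05, 0.06), 0.01)
  q <- cochran_q(pairs)
  w <- (0.1 / 0.01)^2
  expect_equal(q$q_stat, sum(w * (c(0.4, 0.5, 0.6) - 0.5)^2),
               tolerance = 1e-12)
})

test_that("single-pair IVW degenerates to the Wald ratio", {
  p2 <- make_pairs(c(0.1, 0.1), 0.01, c(0.05, 0.05), 0.01)
  fe <- mr_ivw(p2, "fixed")
  w1 <- wald_ratio(p2[1, ])
  expect_equal(fe$beta, w1$beta)
  expect_equal(fe$se, w1$se / sqrt(2))  # two identical instruments
})

test_that("IVW and Egger slope are invariant to jointly negating exposure effects", {
  set.seed(3)
  pairs <- make_pairs(rnorm(8, 0.2, 0.05), 0.01,
                      rnorm(8, 0.06, 0.02), 0.02)
  flipped <- pairs
  flipped$beta_exp <- -flipped$beta_exp
  flipped$beta_out <- -flipped$beta_out
  expect_equal(mr_ivw(pairs)$beta, mr_ivw(flipped)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(pairs)$estimate$beta,
               mr_egger(flipped)$estimate$beta, tolerance = 1e-12)
  expect_equal(mr_egger(pairs)$intercept, mr_egger(flipped)$intercept,
               tolerance = 1e-12)
})

test_that("Egger recovers a noiseless planted intercept and slope to machine tolerance", {
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  pairs <- make_pairs(x, 0.01, 0.05 + 0.3 * x, 0.02)
  e <- mr_egger(pairs)
  expect_equal(e$estimate$beta, 0.3, tolerance = 1e-12)
  expect_equal(e$intercept, 0.05, tolerance = 1e-12)
  # too few instruments: not-applicable, not a crash
  e2 <- mr_egger(pairs[1:2, ])
  expect_false(e2$available)
  expect_true(is.na(e2$estimate$pval))
  # degenerate design
  same_x <- make_pairs(rep(0.2, 4), 0.01, rnorm(4, 0, 0.02), 0.02)
  expect_error(mr_egger(same_x), "degenerate")
})

test_that("weighted median interpolates the cumulative weights correctly", {
  # equal weights, odd J: the middle element
  p3 <- make_pairs(rep(0.1, 3), 0.01, c(0.04, 0.05, 0.09), 0.01)
  wm <- mr_weighted_median(p3, n_boot = 100, seed = 1)
  expect_equal(wm$beta, 0.5)
  # dominant weight pins the estimate: one instrument holds ~90% of weight
  # at ratio 1.0, the others sit at 0.1
  pd <- make_pairs(c(0.3, 0.1, 0.1), c(0.01), c(0.3, 0.01, 0.01),
                   c(0.01, 0.03, 0.03))
  # weights: (0.3/0.01)^2=900 vs (0.1/0.03)^2~11 each
  wmd <- mr_weighted_median(pd, n_boot = 100, seed = 1)
  expect_equal(wmd$beta, 1.0, tolerance = 0.05)
  # brute-force cumulative-weight oracle on random instances
  set.seed(5)
  for (i in 1:10) {
    b <- rnorm(7); w <- runif(7, 0.5, 2)
    wn <- w / sum(w)
    ord <- order(b)
    s <- cumsum(wn[ord]) - wn[ord] / 2
    j <- which(s >= 0.5)[1]
    expected <- if (j == 1) b[ord][1] else
      b[ord][j - 1] + (b[ord][j] - b[ord][j - 1]) *
        (0.5 - s[j - 1]) / (s[j] - s[j - 1])
    expect_equal(targetMR:::weighted_median_point(b, w), expected)
  }
  # equal weights equals the plain median on odd J
  for (i in 1:10) {
    b <- rnorm(9)
    expect_equal(targetMR:::weighted_median_point(b, rep(1, 9)), median(b))
  }
})

test_that("weighted median bootstrap SE is deterministic under a fixed seed", {
  set.seed(9)
  pairs <- make_pairs(rnorm(5, 0.2, 0.02), 0.01, rnorm(5, 0.06, 0.02),
                      0.02)
  a <- mr_weighted_median(pairs, n_boot = 200, seed = 42)
  b <- mr_weighted_median(pairs, n_boot = 200, seed = 42)
  expect_identical(a$se, b$se)
  c <- mr_weighted_median(pairs, n_boot = 200, seed = 43)
  expect_false(identical(a$se, c$se))
  expect_equal(mr_weighted_median(pairs[1:2, ])$method, "weighted_median")
  expect_true(is.na(mr_weighted_median(pairs[1:2, ])$beta))
})

test_that("mode estimators find the dominant cluster", {
  # ratios {0.5, 0.5, 0.5, 2.0}: simple mode near 0.5, checked against a
  # fine-grid density scan oracle
  pm <- make_pairs(c(0.1, 0.1, 0.1, 0.1), 0.01,
                   c(0.05, 0.05, 0.05, 0.2), 0.01)
  sm <- mr_mode(pm, "simple", n_boot = 50, seed = 1)
  expect_equal(sm$beta, 0.5, tolerance = 0.05)
  ratios <- pm$beta_out / pm$beta_exp
  h <- 0.9 * min(sd(ratios), IQR(ratios) / 1.34) * 4^(-1 / 5)
  grid <- seq(-1, 3, by = 1e-4)
  dens <- vapply(grid, function(g) sum(dnorm(g, ratios, h)), numeric(1))
  expect_equal(sm$beta, grid[which.max(dens)], tolerance = 2e-2)
  # all ratios equal c
  pc <- make_pairs(c(0.1, 0.2, 0.4), 0.01, c(0.07, 0.14, 0.28), 0.01)
  expect_equal(mr_mode(pc, "simple", n_boot = 50, seed = 1)$beta, 0.7)
  # weighted mode follows the dominant-weight cluster at 1.2
  pw <- make_pairs(c(0.3, 0.3, 0.1, 0.1), 0.01,
                   c(0.36, 0.36, 0.02, 0.02), c(0.01, 0.01, 0.05, 0.05))
  wm <- mr_mode(pw, "weighted", n_boot = 50, seed = 1)
  expect_equal(wm$beta, 1.2, tolerance = 0.05)
  expect_true(is.na(mr_mode(pm[1:2, ], "simple")$beta))
})

test_that("MR-PRESSO flags a planted outlier, corrects toward truth, and is deterministic", {
  set.seed(21)
  sim <- simulate_mr_protein(11, gamma = 0.3, seed = 77)
  pairs <- sim$pairs
  # displace one ratio by 10 outcome SEs
  pairs$beta_out[4] <- pairs$beta_out[4] + 10 * pairs$se_out[4]
  pr <- mr_presso(pairs, n_sim = 500, seed = 5)
  expect_true("iv_04" %in% pr$outliers)
  expect_lt(pr$global_pval, 0.05)
  expect_lt(abs(pr$corrected$beta - 0.3), abs(pr$raw$beta - 0.3))
  pr2 <- mr_presso(pairs, n_sim = 500, seed = 5)
  expect_identical(pr2$global_pval, pr$global_pval)
  # concordant instruments: global p large, no outliers
  clean <- simulate_mr_protein(10, gamma = 0.3, seed = 78)$pairs
  pr3 <- mr_presso(clean, n_sim = 500, seed = 5)
  expect_gt(pr3$global_pval, 0.05)
  expect_length(pr3$outliers, 0)
  # p is never exactly zero by construction
  expect_gte(pr$global_pval, 1 / 501)
  # too few instruments: not applicable
  expect_true(is.na(mr_presso(pairs[1:3, ])$global_pval))
})
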