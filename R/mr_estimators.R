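# Two-sample summary-data MR estimators and instrument-level diagnostics.
# All estimators consume harmonized pairs (beta_exp/se_exp, beta_out/se_out
# on a common effect allele) and work on the log-odds (outcome) per SD
# (exposure) scale; odds ratios are produced only at report time.

#' Construct an MR estimate
#'
#' Container for one method's causal estimate. The 95% CI is a normal
#' approximation on the estimation scale (`beta +/- 1.96 se`) unless a t
#' reference with `df` degrees of freedom is requested (MR-Egger).
#'
#' @param method Method tag.
#' @param beta,se Causal effect and standard error.
#' @param pval Two-sided p-value; computed from a normal (or t) reference
#'   when omitted.
#' @param n_snp Number of instruments used.
#' @param extras Named list of method-specific values.
#' @param df Degrees of freedom for a t reference (`NULL` = normal).
#' @return Object of class `mr_estimate`.
#' @export
mr_estimate <- function(method, beta, se, pval = NULL, n_snp,
                        extras = list(), df = NULL) {
  crit <- if (is.null(df)) qnorm(0.975) else qt(0.975, df)
  if (is.null(pval)) {
    z <- beta / se
    pval <- if (is.null(df)) 2 * pnorm(-abs(z)) else 2 * pt(-abs(z), df)
  }
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - crit * se, ci_high = beta + crit * se,
                 pval = clamp_pval(pval), n_snp = as.integer(n_snp),
                 extras = extras),
            class = "mr_estimate")
}

# Not-applicable placeholder (e.g. too few instruments for the method).
mr_na <- function(method, n_snp, reason) {
  structure(list(method = method, beta = NA_real_, se = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, pval = NA_real_,
                 n_snp = as.integer(n_snp), extras = list(reason = reason)),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  if (is.na(x$beta)) {
    cat(sprintf("<mr_estimate> %s: not applicable (%s)\n", x$method,
                x$extras$reason))
  } else {
    cat(sprintf(
      "<mr_estimate> %s: beta %.4f (se %.4f), OR %.3f [%.3f, %.3f], p %.3g, n_snp %d\n",
      x$method, x$beta, x$se, exp(x$beta), exp(x$ci_low), exp(x$ci_high),
      x$pval, x$n_snp))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, beta = x$beta, se = x$se,
             or = exp(x$beta), ci_low = x$ci_low, ci_high = x$ci_high,
             pval = x$pval, n_snp = x$n_snp, stringsAsFactors = FALSE)
}

# Per-variant ratio estimates and first-order delta weights shared by the
# ratio-form estimators: beta_j = bout/bexp, se_j = se_out/|bexp|,
# w_j = 1/se_j^2.
ratio_stats <- function(pairs) {
  if (any(pairs$beta_exp == 0))
    stop("beta_exp must be nonzero for ratio estimates", call. = FALSE)
  b <- pairs$beta_out / pairs$beta_exp
  se <- pairs$se_out / abs(pairs$beta_exp)
  list(beta = b, se = se, w = 1 / se^2)
}

#' Wald ratio estimate from a single instrument
#'
#' `beta = beta_out / beta_exp` with the first-order delta-rule standard
#' error `se_out / |beta_exp|`; two-sided normal p-value.
#'
#' @param pair One-row harmonized pair.
#' @return [mr_estimate()] with method `"wald_ratio"`.
#' @export
wald_ratio <- function(pair) {
  if (nrow(pair) != 1L) stop("wald_ratio expects exactly one pair",
                             call. = FALSE)
  rs <- ratio_stats(pair)
  mr_estimate("wald_ratio", rs$beta, rs$se, n_snp = 1L)
}

#' Inverse-variance-weighted estimate
#'
#' Inverse-variance-weighted mean of the per-variant ratio estimates.
#' Fixed-effect SE is `(sum w)^{-1/2}`; the multiplicative random-effects
#' variant scales it by `max(1, sqrt(Q/(J-1)))`, inflating the SE under
#' overdispersion but never deflating it.
#'
#' @param pairs Harmonized pairs (>= 2 rows; use [wald_ratio()] for one).
#' @param mode `"fixed"` or `"multiplicative_random"`.
#' @return [mr_estimate()] with method `"ivw_fe"` or `"ivw_mre"`; extras
#'   carry `q_stat`, `q_df`, `q_pval` and the mre `scale`.
#' @export
mr_ivw <- function(pairs, mode = c("fixed", "multiplicative_random")) {
  mode <- match.arg(mode)
  if (nrow(pairs) < 2L)
    stop("IVW needs >= 2 instruments; use wald_ratio()", call. = FALSE)
  rs <- ratio_stats(pairs)
  beta <- sum(rs$w * rs$beta) / sum(rs$w)
  se_fixed <- 1 / sqrt(sum(rs$w))
  q <- sum(rs$w * (rs$beta - beta)^2)
  df <- nrow(pairs) - 1L
  scale <- max(1, sqrt(q / df))
  se <- if (mode == "fixed") se_fixed else se_fixed * scale
  mr_estimate(if (mode == "fixed") "ivw_fe" else "ivw_mre", beta, se,
              n_snp = nrow(pairs),
              extras = list(q_stat = q, q_df = df,
                            q_pval = clamp_pval(pchisq(q, df,
                                                       lower.tail = FALSE)),
                            scale = scale))
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum w_j (beta_j - beta_IVW)^2` around the fixed-effect IVW
#' estimate, referred to chi-square with J - 1 degrees of freedom.
#'
#' @param pairs Harmonized pairs (>= 2 rows).
#' @return List with `q_stat`, `q_df`, `q_pval`.
#' @export
cochran_q <- function(pairs) {
  est <- mr_ivw(pairs, "fixed")
  est$extras[c("q_stat", "q_df", "q_pval")]
}

#' MR-Egger regression
#'
#' Pairs are first oriented so every exposure effect is non-negative (both
#' betas negated where needed); then weighted least squares of `beta_out`
#' on `beta_exp` with an intercept, weights `1/se_out^2`. A nonzero
#' intercept indicates directional pleiotropy; the slope is the
#' pleiotropy-adjusted causal estimate. Standard errors use multiplicative
#' residual scaling `max(1, sigma_hat)` and a t reference with J - 2
#' degrees of freedom.
#'
#' @param pairs Harmonized pairs; needs >= 3 rows (df >= 1 after slope and
#'   intercept), otherwise a not-applicable result is returned.
#' @return List with `estimate` ([mr_estimate()], method `"egger"`),
#'   `intercept`, `intercept_se`, `intercept_pval`, `available`.
#' @export
mr_egger <- function(pairs) {
  j <- nrow(pairs)
  if (j < 3L)
    return(list(estimate = mr_na("egger", j, "fewer than 3 instruments"),
                intercept = NA_real_, intercept_se = NA_real_,
                intercept_pval = NA_real_, available = FALSE))
  flip <- sign(pairs$beta_exp) < 0
  x <- abs(pairs$beta_exp)
  y <- ifelse(flip, -pairs$beta_out, pairs$beta_out)
  w <- 1 / pairs$se_out^2
  if (var(x) == 0)
    stop("degenerate design: all exposure effects equal", call. = FALSE)
  xm <- sum(w * x) / sum(w)
  ym <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - xm)^2)
  slope <- sum(w * (x - xm) * (y - ym)) / sxx
  intercept <- ym - slope * xm
  res <- y - intercept - slope * x
  df <- j - 2L
  sigma2 <- sum(w * res^2) / df
  scale <- max(1, sqrt(sigma2))
  se_slope <- scale / sqrt(sxx)
  se_int <- scale * sqrt(1 / sum(w) + xm^2 / sxx)
  int_p <- clamp_pval(2 * pt(-abs(intercept / se_int), df))
  list(estimate = mr_estimate("egger", slope, se_slope, n_snp = j, df = df,
                              extras = list(intercept = intercept,
                                            intercept_se = se_int,
                                            intercept_pval = int_p,
                                            scale = scale)),
       intercept = intercept, intercept_se = se_int,
       intercept_pval = int_p, available = TRUE)
}

# Weighted-median point estimate: order the values, form cumulative
# half-open weight midpoints, and interpolate at 0.5.
weighted_median_point <- function(b, w) {
  ord <- order(b)
  b <- b[ord]; w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1L] >= 0.5) return(b[1L])
  if (s[length(s)] < 0.5) return(b[length(b)])
  j <- which(s >= 0.5)[1L]
  b[j - 1L] + (b[j] - b[j - 1L]) * (0.5 - s[j - 1L]) / (s[j] - s[j - 1L])
}

#' Weighted-median estimate
#'
#' Consistent when instruments carrying at least half of the inverse-
#' variance weight are valid. The point estimate interpolates the ordered
#' ratio estimates at the 50% point of the cumulative weights; the SE is
#' the standard deviation of the estimate over seeded parametric bootstrap
#' resamples (exposure and outcome effects redrawn from normals with their
#' reported SEs).
#'
#' @param pairs Harmonized pairs; needs >= 3 rows, otherwise
#'   not-applicable.
#' @param n_boot Bootstrap resamples (default 5000).
#' @param seed RNG seed for the bootstrap (the ambient stream is
#'   untouched).
#' @return [mr_estimate()] with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(pairs, n_boot = 5000, seed = NULL) {
  j <- nrow(pairs)
  if (j < 3L) return(mr_na("weighted_median", j, "fewer than 3 instruments"))
  rs <- ratio_stats(pairs)
  point <- weighted_median_point(rs$beta, rs$w)
  se <- with_seed(seed, {
    boot <- vapply(seq_len(n_boot), function(i) {
      be <- rnorm(j, pairs$beta_exp, pairs$se_exp)
      bo <- rnorm(j, pairs$beta_out, pairs$se_out)
      ok <- be != 0
      weighted_median_point(bo[ok] / be[ok],
                            (abs(be[ok]) / pairs$se_out[ok])^2)
    }, numeric(1))
    sd(boot)
  })
  mr_estimate("weighted_median", point, se, n_snp = j)
}

# Mode of a weighted normal-kernel density over the ratio estimates.
# Bandwidth: phi x Silverman's rule; all-equal input short-circuits.
kde_mode <- function(b, w, phi = 1) {
  if (length(unique(b)) == 1L) return(b[1L])
  s <- min(sd(b), stats::IQR(b) / 1.34)
  if (s == 0) s <- sd(b)
  h <- phi * 0.9 * s * length(b)^(-1 / 5)
  grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = 512L)
  dens <- colSums(w / sum(w) * outer(b, grid, function(bb, gg)
    stats::dnorm(gg, bb, h)))
  grid[which.max(dens)]
}

#' Mode-based estimate (simple or weighted)
#'
#' Kernel-density mode of the per-variant ratio estimates: the simple mode
#' weights all instruments equally, the weighted mode uses inverse-variance
#' weights. Bandwidth is `phi` times Silverman's rule on the ratios; SE by
#' seeded parametric bootstrap. Consistent when the largest group of
#' instruments with the same ratio is valid.
#'
#' @param pairs Harmonized pairs; needs >= 3 rows, otherwise
#'   not-applicable.
#' @param kind `"simple"` or `"weighted"`.
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return [mr_estimate()] with method `"simple_mode"` or
#'   `"weighted_mode"`.
#' @export
mr_mode <- function(pairs, kind = c("simple", "weighted"), phi = 1,
                    n_boot = 1000, seed = NULL) {
  kind <- match.arg(kind)
  method <- paste0(kind, "_mode")
  j <- nrow(pairs)
  if (j < 3L) return(mr_na(method, j, "fewer than 3 instruments"))
  rs <- ratio_stats(pairs)
  wts <- if (kind == "simple") rep(1, j) else rs$w
  point <- kde_mode(rs$beta, wts, phi)
  se <- with_seed(seed, {
    boot <- vapply(seq_len(n_boot), function(i) {
      be <- rnorm(j, pairs$beta_exp, pairs$se_exp)
      bo <- rnorm(j, pairs$beta_out, pairs$se_out)
      ok <- be != 0
      bb <- bo[ok] / be[ok]
      ww <- if (kind == "simple") rep(1, sum(ok))
            else (abs(be[ok]) / pairs$se_out[ok])^2
      kde_mode(bb, ww, phi)
    }, numeric(1))
    sd(boot)
  })
  mr_estimate(method, point, se, n_snp = j)
}

#' MR-PRESSO global test, outlier detection and corrected estimate
#'
#' Residual-sum-of-squares simulation test for horizontal pleiotropy. Each
#' instrument's observed outcome effect is compared with its leave-one-out
#' IVW prediction; the inverse-variance-weighted residual sum of squares is
#' referred to `n_sim` seeded simulations in which outcome effects are
#' redrawn from normals around the leave-one-out predictions. The global
#' empirical p uses the `(1 + x)/(1 + n)` estimator so it is never zero.
#' Per-instrument outlier p-values come from each instrument's simulated
#' RSS contribution, Bonferroni-adjusted by the number of instruments; the
#' corrected estimate is fixed-effect IVW on the non-outliers.
#'
#' @param pairs Harmonized pairs; needs >= 4 rows, otherwise
#'   not-applicable.
#' @param n_sim Number of simulations (default 1000).
#' @param seed RNG seed for the simulations.
#' @param outlier_alpha Threshold on the Bonferroni-adjusted per-instrument
#'   p (default 0.05).
#' @return List with `global_pval`, `outliers` (variant ids),
#'   `outlier_pvals` (adjusted, named), `raw` (fixed-effect IVW on all
#'   instruments, method `"presso_raw"`) and `corrected`
#'   ([mr_estimate()], method `"presso_corrected"`; not-applicable when
#'   every instrument is flagged).
#' @export
mr_presso <- function(pairs, n_sim = 1000, seed = NULL,
                      outlier_alpha = 0.05) {
  j <- nrow(pairs)
  if (j < 4L)
    return(list(global_pval = NA_real_, outliers = character(0),
                outlier_pvals = numeric(0),
                raw = mr_na("presso_raw", j, "fewer than 4 instruments"),
                corrected = mr_na("presso_corrected", j,
                                  "fewer than 4 instruments")))
  bx <- pairs$beta_exp; by <- pairs$beta_out
  w <- 1 / pairs$se_out^2
  a <- w * bx * by
  k <- w * bx^2
  loo_slope <- (sum(a) - a) / (sum(k) - k)
  pred <- loo_slope * bx
  rss_j <- w * (by - pred)^2
  rss_obs <- sum(rss_j)

  sims <- with_seed(seed, {
    b_sim <- matrix(rnorm(j * n_sim, mean = pred, sd = pairs$se_out),
                    nrow = j)
    a_sim <- w * bx * b_sim
    sa <- colSums(a_sim)
    loo_sim <- sweep(-a_sim, 2, sa, `+`) / (sum(k) - k)
    pred_sim <- loo_sim * bx
    w * (b_sim - pred_sim)^2
  })
  rss_sim <- colSums(sims)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  p_snp <- (1 + rowSums(sims >= rss_j)) / (n_sim + 1)
  p_adj <- pmin(1, p_snp * j)
  names(p_adj) <- pairs$variant_id
  out_idx <- which(p_adj < outlier_alpha)
  keep <- setdiff(seq_len(j), out_idx)

  raw <- mr_ivw(pairs, "fixed")
  raw$method <- "presso_raw"
  corrected <- if (length(keep) >= 2L) {
    est <- mr_ivw(pairs[keep, , drop = FALSE], "fixed")
    est$method <- "presso_corrected"
    est
  } else if (length(keep) == 1L) {
    est <- wald_ratio(pairs[keep, , drop = FALSE])
    est$method <- "presso_corrected"
    est
  } else {
    mr_na("presso_corrected", 0L, "all instruments flagged as outliers")
  }
  list(global_pval = global_p, outliers = pairs$variant_id[out_idx],
       outlier_pvals = p_adj, raw = raw, corrected = corrected)
}

#' Full instrument-level diagnostics for one protein
#'
#' Cochran's Q, the MR-Egger intercept test, and the MR-PRESSO global test
#' and outlier list, with components that are undefined at the available
#' number of instruments reported as NA (and treated as not-detected by
#' [detect_flags()]).
#'
#' @param pairs Harmonized pairs.
#' @param n_presso_sim Simulations for MR-PRESSO.
#' @param seed RNG seed for MR-PRESSO.
#' @return List with `q_stat`, `q_df`, `q_pval`, `egger_intercept`,
#'   `egger_intercept_se`, `egger_intercept_pval`, `presso_global_pval`,
#'   `presso_outliers`.
#' @export
mr_diagnostics <- function(pairs, n_presso_sim = 1000, seed = NULL) {
  j <- nrow(pairs)
  q <- if (j >= 2L) cochran_q(pairs)
       else list(q_stat = NA_real_, q_df = NA_integer_, q_pval = NA_real_)
  eg <- mr_egger(pairs)
  pr <- mr_presso(pairs, n_sim = n_presso_sim, seed = seed)
  list(q_stat = q$q_stat, q_df = q$q_df, q_pval = q$q_pval,
       egger_intercept = eg$intercept,
       egger_intercept_se = eg$intercept_se,
       egger_intercept_pval = eg$intercept_pval,
       presso_global_pval = pr$global_pval,
       presso_outliers = pr$outliers)
}
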