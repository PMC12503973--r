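---
title: "Triangulating protein drug targets with summary-data Mendelian randomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangulating protein drug targets with summary-data Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetMR)
```

## The problem

Circulating plasma proteins are attractive drug targets: genetic variants
near a protein's encoding gene (cis-pQTLs) shift its abundance for life,
so comparing disease risk across pQTL genotypes approximates a randomized
trial of modulating that protein. `targetMR` implements the full
triangulation pipeline for this design on summary statistics alone:
instrument selection, a suite of two-sample Mendelian randomization (MR)
estimators with a diagnostics-driven adjudication rule, Bonferroni
discovery/replication logic, Bayesian colocalization, and SMR with the
HEIDI linkage test — plus a summary-level simulator with known ground
truth that makes every stage testable without any individual-level or
controlled-access data.

## Instrument selection

For each protein the exposure variants pass four gates:

1. **cis window** — variants within 1 Mb of the gene body
   (`select_cis()`); a cis instrument acts near its own gene, which
   limits horizontal pleiotropy.
2. **relevance** — genome-wide significance, strictly `p < 5e-8`
   (`filter_pvalue()`).
3. **independence** — greedy LD clumping (`ld_clump()`): repeatedly keep
   the smallest-p variant and discard neighbours within 1000 kb with
   `r² ≥ 0.1`. A `"stringent"` preset (`r² < 0.001`, 10,000 kb) is also
   shipped; the defaults are the working values, the stringent preset the
   conservative alternative used when near-independence must be enforced.
4. **strength** — per-variant `R² = 2·EAF·(1−EAF)·β²`
   (`variance_explained()`) and
   `F = R²(N−K−1)/((1−R²)K)` (`f_statistic()`), keeping instruments with
   `F > 10` strictly (`filter_weak()`). Filtering is per-variant
   (`K = 1`); an overall F with `K` = instrument count and summed `R²` is
   reported for audit. The `"as_printed"` formula variant substitutes
   `(1+R²)` in the denominator — a form occasionally seen in the applied
   literature; it gives slightly smaller F values and is exposed purely
   for auditability, with `"standard"` the default.

Harmonization (`harmonize()`) expresses exposure and outcome effects on a
common effect allele: swapped alleles negate the outcome beta and mirror
its frequency. Palindromic variants (A/T, C/G) cannot be oriented from
allele labels; they are aligned by allele frequency unless either trait's
EAF falls in [0.42, 0.58], in which case they are dropped as ambiguous.
This band, the indel exclusion, and the forward-strand assumption are
explicit, configurable policies — summary data cannot recover strand, so
no inference beyond the palindrome logic is attempted.

## The estimator suite and adjudication

All estimators work on per-variant ratio estimates
`β_j = β_out,j / β_exp,j` with first-order delta weights
`w_j = (β_exp,j / se_out,j)²`, on the log-odds (outcome) per SD
(exposure) scale. Odds ratios are exponentiated only at report time.

* `wald_ratio()` — single instrument, `se = se_out/|β_exp|`.
* `mr_ivw()` — inverse-variance-weighted mean; fixed-effect SE
  `(Σw)^{-1/2}`, or multiplicative random effects scaling the SE by
  `max(1, √(Q/(J−1)))`. The floor at 1 prevents anti-conservative SEs
  when instruments under-disperse.
* `cochran_q()` — heterogeneity around the fixed-effect estimate,
  chi-square with `J−1` df.
* `mr_egger()` — weighted regression with an intercept after orienting
  all exposure effects positive; the intercept estimates the mean
  directional pleiotropic effect, the slope is the adjusted causal
  estimate. SEs use multiplicative residual scaling `max(1, σ̂)` and a t
  reference with `J−2` df — the standard small-J practice. Note the
  scaling means a perfectly interpolating fit still reports the
  weight-implied SE, not zero.
* `mr_weighted_median()` — interpolated 50% point of the
  inverse-variance-weighted ordered ratios; valid while ≥ 50% of weight
  comes from valid instruments. SE by seeded parametric bootstrap
  (default 5000 resamples).
* `mr_mode()` — simple and weighted kernel-density modes (normal kernel,
  bandwidth `φ ×` Silverman's rule on the ratios, `φ = 1` by default);
  sensitivity estimators, not adjudication candidates.
* `mr_presso()` — residual-sum-of-squares simulation test: each
  instrument's outcome effect is compared with its leave-one-out IVW
  prediction, the weighted RSS is referred to seeded simulations, and the
  empirical p uses `(1+x)/(1+n)` so it is never zero. Per-instrument
  contributions, Bonferroni-adjusted by J, flag outliers; the corrected
  estimate is IVW on the survivors.

`detect_flags()` marks heterogeneity when Cochran's Q has `p < 0.05` and
pleiotropy when either the Egger intercept or the MR-PRESSO global test
has `p < 0.05` (strict). `choose_primary()` then applies the selection
tree: one instrument → Wald ratio; no flags → fixed-effect IVW (the
no-heterogeneity default is fixed-effect, with the random-effects variant
a configuration switch); heterogeneity only → the larger-p of weighted
median and multiplicative-random-effects IVW; pleiotropy only → the
larger-p of Egger and PRESSO-corrected; both → the largest p among those
four. Ties take the earlier method in that order; methods undefined at
the instrument count are excluded and recorded. Choosing the *largest*
p deliberately prefers the most conservative robust estimate.

Discovery significance uses Bonferroni with m = the number of proteins
with a valid estimate. A protein is **prioritized**
(`replication_consistency()`) when its discovery estimate is significant,
at least one replication combination is significant under its own
Bonferroni denominator, and all significant estimates share the
discovery's direction. "At least one" rather than "all" is the default
because replication combinations cover different protein subsets; an
`"all"` mode exists. The direction requirement is this package's
addition and can be disabled. Cross-cohort pooling (`meta_fixed()`) is
fixed-effect inverse-variance — the smallest assumption set given two to
four estimates per protein; a random-effects pool is a natural extension
but is not what the evidence table reports.

## Colocalization

`coloc_abf()` enumerates single-causal-variant configurations with
Wakefield approximate Bayes factors,
`log ABF = ½log(1−r) + ½ r z²` with `r = W/(W+V)`, prior effect SD
`√W` = 0.15 for quantitative traits and 0.2 for case-control traits, and
priors `p1 = p2 = 1e-4`, `p12 = 1e-5` — the long-standing conventional
defaults, all exposed. Sums run in log space (log-sum-exp); the
distinct-variant term H3 is the log-difference
`ΣABF1·ΣABF2 − Σ(ABF1·ABF2)`, exactly zero mass for a single-variant
locus. PP4 > 0.80 (strict) claims a shared causal variant. The
single-causal-variant assumption is retained deliberately; multi-signal
fine-mapping is out of scope, and loci with several independent signals
should be interpreted cautiously.

## SMR and HEIDI

`smr_test()` tests the protein→disease effect at the top cis variant:
`T = z_GWAS² z_QTL² / (z_GWAS² + z_QTL²)` on chi-square(1), with
`b_SMR = b_GWAS / b_QTL`. `heidi_select()` takes LD partners of the top
variant with `r² ∈ [0.05, 0.9]` and QTL `z² > 10` (at most 20, highest r²
first — the cited tool's documented conventions, configurable);
`heidi_test()` compares their SMR ratios with the top variant's,
propagating GWAS and QTL sampling error and LD through the delta method,
and refers `Σ z_d²` to a correlated chi-square sum via the eigenvalues of
the z_d correlation matrix with a Satterthwaite–Welch two-moment
(scaled chi-square) tail. Two-moment matching was chosen over exact
numerical inversion for determinism and light dependencies; against a
Monte-Carlo reference its error is well inside the decision margins the
pipeline uses (the HEIDI decision threshold is 0.05, and simulation
checks below exercise both regimes). A HEIDI p ≤ 0.05 says the signal
looks like *linkage* of distinct variants, not a shared one;
`classify_smr()` passes a protein that clears the SMR Bonferroni family
and has HEIDI p > 0.05. Near-singular covariance (very high mutual LD) is
ridge-regularized by 1e-8 on the diagonal with a warning.

## The simulator and what it does (not) emulate

All generators are pure functions of (configuration, seed).

`simulate_locus()` draws marginal summary statistics for m = 50 variants
under AR(1) LD (`ρ = 0.9`): standardized-genotype model, marginal means
`R·b`, covariance `R/n_eff`, with `n_eff = n` for the quantitative
exposure and `n·cf·(1−cf)` for the case-control outcome on the log-odds
scale. Defaults mirror the study conditions the package targets: pQTL
cohort n = 54,219; GWAS n = 306,075 with case fraction 7589/306,075.
Architectures H0–H4 (null / protein-only / disease-only / linkage /
shared variant) size causal effects from target top z-scores (10 for the
exposure, 8 for the outcome), i.e. clearly genome-wide-significant,
well-powered signals. Under H4 a non-NULL `gamma` ties the outcome's
causal effect to `gamma ×` the exposure effect plus a direct term.

`simulate_mr_protein()` abstracts post-clumping instruments: independent
variants, per-variant F uniform in [100, 1000] (strong cis-pQTLs),
oriented to the protein-increasing allele — the orientation matters
because *directional* pleiotropy is only defined relative to it. Outcome
effects are `γ·β_exp + α_j` with `α_j ~ N(pleiotropy_mean,
pleiotropy_sd)`; an outlier fraction receives an extra ±10 outcome-SE
displacement with ids recorded. `simulate_proteome()` stacks independent
proteins with a stated causal fraction for pipeline-level power and
family-wise-error checks.

What the simulator does **not** emulate: sample overlap between exposure
and outcome cohorts, liability-scale case-control genetics (effects are
generated directly on the log-odds scale with effective-n variance
scaling), real-genome LD (AR(1) decay only), allele-frequency-dependent
effect-size architecture, winner's curse in instrument discovery, and
assay/platform differences between proteomic technologies. Tests passing
on this generator therefore certify the *statistical machinery* —
estimator arithmetic, calibration, decision rules — not robustness to
those real-data complications.

## Numerical choices

* p-values are clamped to `(0, 1]`; empirical p-values use `(1+x)/(1+n)`.
* The mre-IVW and Egger residual scales are floored at 1.
* Log-space colocalization with log-sum-exp and log-difference; the
  enumeration identity is verified against linear-space arithmetic to
  1e-9 on small loci.
* Greedy clumping breaks p-value ties by position, then lexicographic id,
  making selection order deterministic.
* Bootstrap and simulation seeds are arguments everywhere, derived
  sub-seeds stay below 2³¹, and the ambient RNG stream is always
  restored.
* Degenerate inputs fail loudly: zero exposure effect in a ratio, all
  instruments flagged as outliers, empty variant intersections, singular
  HEIDI covariance (warned and ridged), `n ≤ k+1` in the F-statistic.

## Problem sizes used in the checks

The shipped verification suite uses: 2000 replicates for IVW type-I
error and SMR null calibration, 1000 for CI coverage, 200 loci per
colocalization architecture, 500 replicates for Egger intercept
recovery, 100 for MR-PRESSO outlier detection, and 200 each for the
HEIDI linkage/shared comparisons; the workflow in `analysis/` simulates
a 60-protein proteome with 6 causal proteins. These sizes give Monte
Carlo standard errors comfortably below the decision margins being
checked. For the architecture-recovery check the linkage scenario uses
well-separated causal variants (r² ≈ 0): with r² ≈ 0.5 between the two
causal variants, H3 versus H4 is genuinely ambiguous for
single-causal-variant colocalization — that regime is exactly what the
HEIDI test is for, and the HEIDI checks use it.

## Known limitations

* Single-causal-variant colocalization; no SuSiE-style multi-signal
  decomposition.
* No MR-RAPS, CAUSE, or multivariable MR; no FDR alternatives to
  Bonferroni.
* First-order delta weights in the ratio estimators (no second-order or
  exact weighting); weak instruments are excluded rather than modelled.
* No genome-build liftover, reference-panel allele lookup, or LD
  computation from genotypes — the LD matrix is an input.
* The evidence table's replication p is the best (smallest) across
  combinations; per-combination detail lives in the replication output.
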