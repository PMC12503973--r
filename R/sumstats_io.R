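# Reading, validation and allele harmonization of GWAS / pQTL summary
# statistics. All downstream estimation assumes records that passed the
# row-level invariants enforced here, and exposure/outcome effects expressed
# on a common effect allele.

.SUMSTATS_FIELDS <- c("variant_id", "chrom", "pos", "effect_allele",
                      "other_allele", "eaf", "beta", "se", "pval", "n")
.SUMSTATS_OPTIONAL <- c("n_case", "n_control")
.NUMERIC_FIELDS <- c("pos", "eaf", "beta", "se", "pval", "n",
                     "n_case", "n_control")

#' Default column mapping for summary-statistics files
#'
#' A dialect maps the internal field names to the column names used in a
#' particular file. The default is the identity mapping on the internal
#' schema: `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#' `eaf`, `beta`, `se`, `pval`, `n` (plus optional `n_case`, `n_control`).
#'
#' @return Named list mapping internal field names to column names.
#' @export
default_dialect <- function() {
  as.list(setNames(c(.SUMSTATS_FIELDS, .SUMSTATS_OPTIONAL),
                   c(.SUMSTATS_FIELDS, .SUMSTATS_OPTIONAL)))
}

#' Read and validate summary statistics
#'
#' Reads a tab- or comma-delimited summary-statistics file with a header,
#' renames columns according to `dialect`, and enforces the per-variant
#' invariants: single-nucleotide A/C/G/T alleles with effect allele
#' different from the other allele, `se > 0`, `eaf` strictly inside (0, 1),
#' `pval` in (0, 1], and positive `n`. Rows violating an invariant are
#' rejected (not an error) and reported with a per-row reason; a missing
#' mandatory column is a configuration error.
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect Named list mapping internal field names to file column
#'   names, or a path to a YAML file containing such a mapping. Defaults to
#'   [default_dialect()].
#' @param trait_type `"quantitative"` (e.g. protein levels, effects in SD
#'   units) or `"case_control"` (effects on the log-odds scale).
#' @param sep Field separator; by default sniffed from the header line
#'   (tab if present, comma otherwise).
#' @return List with elements `records` (data frame of retained rows on the
#'   internal schema, plus `trait_type`), `rejections` (data frame with
#'   `row`, `variant_id`, `reason`), and `n_rejected`.
#' @export
read_sumstats <- function(path, dialect = default_dialect(),
                          trait_type = c("quantitative", "case_control"),
                          sep = NULL) {
  trait_type <- match.arg(trait_type)
  if (is.character(dialect) && length(dialect) == 1L)
    dialect <- yaml::read_yaml(dialect)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- read.table(path, header = TRUE, sep = sep, quote = "\"",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  missing <- vapply(.SUMSTATS_FIELDS, function(f) {
    is.null(dialect[[f]]) || !(dialect[[f]] %in% names(raw))
  }, logical(1))
  if (any(missing))
    stop("missing mandatory column(s): ",
         paste(.SUMSTATS_FIELDS[missing], collapse = ", "), call. = FALSE)

  fields <- c(.SUMSTATS_FIELDS,
              .SUMSTATS_OPTIONAL[vapply(.SUMSTATS_OPTIONAL, function(f)
                !is.null(dialect[[f]]) && dialect[[f]] %in% names(raw),
                logical(1))])
  rec <- as.data.frame(lapply(setNames(fields, fields), function(f)
    raw[[dialect[[f]]]]), stringsAsFactors = FALSE)
  for (f in intersect(.NUMERIC_FIELDS, names(rec)))
    rec[[f]] <- suppressWarnings(as.numeric(rec[[f]]))
  rec$effect_allele <- toupper(rec$effect_allele)
  rec$other_allele <- toupper(rec$other_allele)

  reason <- validate_rows(rec)
  keep <- is.na(reason)
  rejections <- data.frame(row = which(!keep),
                           variant_id = rec$variant_id[!keep],
                           reason = reason[!keep],
                           stringsAsFactors = FALSE)
  records <- rec[keep, , drop = FALSE]
  rownames(records) <- NULL
  records$trait_type <- trait_type
  list(records = records, rejections = rejections,
       n_rejected = nrow(rejections))
}

# First failing invariant per row, NA for valid rows. Order matters: it is
# the reason reported in the rejection log.
validate_rows <- function(rec) {
  n <- nrow(rec)
  reason <- rep(NA_character_, n)
  flag <- function(cond, msg) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- msg
  }
  num_bad <- Reduce(`|`, lapply(intersect(c("pos", "eaf", "beta", "se",
                                            "pval", "n"), names(rec)),
                                function(f) is.na(rec[[f]])))
  flag(num_bad, "unparseable numeric")
  snv <- grepl("^[ACGT]$", rec$effect_allele) &
    grepl("^[ACGT]$", rec$other_allele)
  multi <- nchar(rec$effect_allele) > 1L | nchar(rec$other_allele) > 1L
  flag(multi, "indel alleles not supported")
  flag(!snv & !multi, "allele not in A/C/G/T")
  flag(rec$effect_allele == rec$other_allele, "identical alleles")
  flag(rec$se <= 0, "nonpositive SE")
  flag(rec$eaf <= 0 | rec$eaf >= 1, "EAF out of (0,1)")
  flag(rec$pval <= 0 | rec$pval > 1, "p-value out of (0,1]")
  flag(rec$n <= 0, "nonpositive sample size")
  reason
}

#' Write summary statistics or any results table as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Is an allele pair palindromic?
#'
#' A/T and C/G pairs (in either order) are strand-ambiguous: the same pair
#' read from the opposite strand is indistinguishable from an allele swap.
#'
#' @param effect_allele,other_allele Single-nucleotide alleles (A/C/G/T).
#' @return Logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  a1 <- toupper(effect_allele); a2 <- toupper(other_allele)
  ok <- grepl("^[ACGT]$", a1) & grepl("^[ACGT]$", a2)
  if (!all(ok))
    stop("alleles must be single nucleotides in A/C/G/T", call. = FALSE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  unname(comp[a1] == a2)
}

#' Harmonize exposure and outcome summary statistics to a common allele
#'
#' Joins exposure (pQTL) and outcome (disease GWAS) records by
#' `variant_id` and expresses both effects on the exposure's effect allele.
#' When the outcome's alleles are swapped relative to the exposure, the
#' outcome beta is negated and its EAF replaced by `1 - eaf`
#' (`flag = "flipped"`). Palindromic variants (A/T, C/G) cannot be oriented
#' by allele labels; they are aligned by allele frequency unless either
#' trait's EAF lies in `[palindromic_eaf_limit, 1 - palindromic_eaf_limit]`,
#' in which case they are dropped as ambiguous. Variants absent from the
#' outcome, or with incompatible alleles, are dropped with a reason. Every
#' exposure variant appears exactly once in the output with exactly one
#' flag; inputs are assumed forward-strand.
#'
#' @param exposure,outcome Record data frames as returned by
#'   [read_sumstats()]`$records` (minimally: `variant_id`, alleles, `eaf`,
#'   `beta`, `se`; `n` is carried through when present).
#' @param palindromic_eaf_limit Lower bound of the ambiguous EAF band
#'   (default 0.42, i.e. drop when MAF is in \[0.42, 0.5\] on either side).
#' @return Data frame of harmonized pairs: `variant_id`, `effect_allele`,
#'   `other_allele`, `eaf_exp`, `beta_exp`, `se_exp`, `eaf_out`,
#'   `beta_out`, `se_out`, `n_exp`, `n_out`, `flag`, `reason`. Flags are
#'   `aligned`, `flipped`, `dropped_palindromic`, `dropped_mismatch`;
#'   dropped rows are excluded from estimation (see [harmonized_kept()]).
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_limit = 0.42) {
  for (nm in c("exposure", "outcome")) {
    ids <- get(nm)$variant_id
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
      stop(sprintf("duplicate variant_id in %s: %s", nm,
                   paste(dup, collapse = ", ")), call. = FALSE)
  }
  idx <- match(exposure$variant_id, outcome$variant_id)
  n <- nrow(exposure)
  out <- data.frame(
    variant_id = exposure$variant_id,
    effect_allele = exposure$effect_allele,
    other_allele = exposure$other_allele,
    eaf_exp = exposure$eaf, beta_exp = exposure$beta, se_exp = exposure$se,
    eaf_out = NA_real_, beta_out = NA_real_, se_out = NA_real_,
    n_exp = if ("n" %in% names(exposure)) exposure$n else NA_real_,
    n_out = NA_real_,
    flag = NA_character_, reason = NA_character_,
    stringsAsFactors = FALSE)

  for (i in seq_len(n)) {
    j <- idx[i]
    if (is.na(j)) {
      out$flag[i] <- "dropped_mismatch"
      out$reason[i] <- "absent from outcome"
      next
    }
    ea_e <- exposure$effect_allele[i]; oa_e <- exposure$other_allele[i]
    ea_o <- outcome$effect_allele[j]; oa_o <- outcome$other_allele[j]
    b_o <- outcome$beta[j]; f_o <- outcome$eaf[j]
    same <- ea_o == ea_e && oa_o == oa_e
    swapped <- ea_o == oa_e && oa_o == ea_e
    if (!same && !swapped) {
      out$flag[i] <- "dropped_mismatch"
      out$reason[i] <- "allele mismatch"
      next
    }
    pal <- is_palindromic(ea_e, oa_e)
    if (pal) {
      lim <- palindromic_eaf_limit
      ambiguous <- function(f) f >= lim && f <= 1 - lim
      if (ambiguous(exposure$eaf[i]) || ambiguous(f_o)) {
        out$flag[i] <- "dropped_palindromic"
        out$reason[i] <- "ambiguous palindromic variant"
        next
      }
      # allele labels are uninformative for palindromes: orient by which
      # side of 0.5 the frequencies fall on
      if ((exposure$eaf[i] < 0.5) == (f_o < 0.5)) {
        out$flag[i] <- "aligned"
      } else {
        out$flag[i] <- "flipped"
        b_o <- -b_o; f_o <- 1 - f_o
      }
    } else if (same) {
      out$flag[i] <- "aligned"
    } else {
      out$flag[i] <- "flipped"
      b_o <- -b_o; f_o <- 1 - f_o
    }
    out$eaf_out[i] <- f_o
    out$beta_out[i] <- b_o
    out$se_out[i] <- outcome$se[j]
    if ("n" %in% names(outcome)) out$n_out[i] <- outcome$n[j]
  }
  out
}

#' Retained harmonized pairs
#'
#' Subset of [harmonize()] output usable for estimation (flag `aligned` or
#' `flipped`).
#'
#' @param pairs Output of [harmonize()].
#' @return Data frame.
#' @export
harmonized_kept <- function(pairs) {
  out <- pairs[pairs$flag %in% c("aligned", "flipped"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
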