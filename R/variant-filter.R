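# High-confidence somatic variant filtering from read-level evidence.
#
# Candidate calls arrive pre-called and pre-annotated (e.g. from a
# VarScan2-style tumor/normal caller); this module applies the
# read-evidence criteria that separate high-confidence somatic SNVs and
# InDels from artifacts.

#' Construct and validate a table of candidate variants
#'
#' A candidate variant carries the read-level evidence needed by the
#' somatic filters: depths and alt counts in tumor and normal, plus (for
#' SNVs) the mapping/base qualities of mutant-supporting reads and the
#' distances of mutant- and reference-supporting reads to the nearer read
#' end. Quality and distance vectors are stored as list-columns; in the
#' TSV dialect they are semicolon-separated.
#'
#' @param df a data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `variant_class` (one of SNV/insertion/deletion), `effect`,
#'   `tumor_depth`, `tumor_alt_count`, `normal_depth`, `normal_alt_count`,
#'   and, for SNVs, list-columns `mutant_mapqs`, `mutant_baseqs`,
#'   `mutant_end_distances`, `ref_end_distances`; indels additionally use
#'   a logical `germline_flag`.
#' @return the validated data.frame, with an `id` column added when absent.
#' @export
candidate_variants <- function(df) {
  req <- c("chrom", "pos", "ref", "alt", "variant_class", "effect",
           "tumor_depth", "tumor_alt_count", "normal_depth",
           "normal_alt_count")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stopf("candidate table is missing required column(s): %s",
          paste(miss, collapse = ", "))
  }
  if (!"id" %in% names(df)) {
    df$id <- sprintf("var%04d", seq_len(nrow(df)))
  }
  bad <- which(df$pos < 1)
  if (length(bad)) stopf("pos must be >= 1 (row %d)", bad[1])
  bad <- which(df$tumor_alt_count > df$tumor_depth)
  if (length(bad)) stopf("tumor_alt_count exceeds tumor_depth (row %d)", bad[1])
  bad <- which(df$normal_alt_count > df$normal_depth)
  if (length(bad)) stopf("normal_alt_count exceeds normal_depth (row %d)", bad[1])
  bad <- which(!df$variant_class %in% c("SNV", "insertion", "deletion"))
  if (length(bad)) stopf("unknown variant_class '%s' (row %d)",
                         df$variant_class[bad[1]], bad[1])
  bad <- which(!df$effect %in% EFFECT_LEVELS)
  if (length(bad)) stopf("unknown effect '%s' (row %d)",
                         df$effect[bad[1]], bad[1])
  for (col in c("mutant_mapqs", "mutant_baseqs", "mutant_end_distances",
                "ref_end_distances")) {
    if (col %in% names(df) && !is.list(df[[col]])) {
      stopf("column %s must be a list-column of numeric vectors", col)
    }
  }
  df
}

#' One-sided rank test of quality values against a fixed threshold
#'
#' Tests whether a sample of per-read qualities is significantly above a
#' constant threshold, via a one-sided Wilcoxon signed-rank test on the
#' differences (value - threshold). Zero differences are dropped by
#' default (`zero_method = "wilcox"`); `"pratt"` keeps them in the
#' ranking and uses a normal approximation. The exact null distribution
#' is used for n <= 25 without tied absolute differences, the
#' (continuity-corrected, tie-corrected) normal approximation otherwise.
#'
#' @param values numeric vector of qualities (must be non-empty).
#' @param threshold the constant to test against.
#' @param alternative "greater" (default): values exceed the threshold.
#' @param zero_method how zero differences are handled.
#' @return the p-value.
#' @export
rank_test_vs_threshold <- function(values, threshold,
                                   alternative = "greater",
                                   zero_method = c("wilcox", "pratt")) {
  zero_method <- match.arg(zero_method)
  alternative <- match.arg(alternative, c("greater", "less", "two.sided"))
  values <- as.numeric(values)
  if (length(values) == 0 || all(is.na(values))) {
    stopf("insufficient evidence: empty quality list")
  }
  if (any(values < 0, na.rm = TRUE)) stopf("qualities must be >= 0")
  d <- values[!is.na(values)] - threshold
  if (zero_method == "pratt") {
    return(signed_rank_pratt(d, alternative))
  }
  d <- d[d != 0]
  if (length(d) == 0) return(1)  # all at the threshold: no evidence
  use_exact <- length(d) <= 25 && anyDuplicated(abs(d)) == 0
  suppressWarnings(
    stats::wilcox.test(d, alternative = alternative, exact = use_exact)$p.value
  )
}

# Pratt signed-rank: zeros participate in ranking but contribute no signed
# rank; normal approximation with zero and tie corrections.
signed_rank_pratt <- function(d, alternative) {
  n <- length(d)
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  n0 <- sum(d == 0)
  mu <- (n * (n + 1) / 2 - n0 * (n0 + 1) / 2) / 2
  tie_tab <- table(r[d != 0])
  v <- n * (n + 1) * (2 * n + 1) / 24 -
    n0 * (n0 + 1) * (2 * n0 + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  if (v <= 0) return(1)
  z <- (w_pos - mu) / sqrt(v)
  switch(alternative,
         greater = stats::pnorm(z, lower.tail = FALSE),
         less = stats::pnorm(z),
         two.sided = 2 * stats::pnorm(-abs(z)))
}

evidence_ok <- function(x) {
  !is.null(x) && length(x) > 0 && !all(is.na(x))
}

#' Filter candidate somatic SNVs on read-level evidence
#'
#' A candidate passes only if all eight criteria hold:
#' \enumerate{
#'   \item tumor and normal depth both >= 10x;
#'   \item tumor VAF >= 5\% and normal VAF < 2\%;
#'   \item at least 3 mutant-supporting reads in the tumor;
#'   \item more than 10 bp from the nearest other candidate SNV on the
#'     same chromosome (both members of a too-close pair fail);
#'   \item mutant-read mapping qualities significantly above 30
#'     (one-sided signed-rank, p < 0.2);
#'   \item mutant-read base qualities significantly above 20 (p < 0.05);
#'   \item mutant-supporting reads not significantly closer to read ends
#'     than reference-supporting reads (one-sided rank-sum for "mutant
#'     closer", pass requires p >= 0.1); the fraction of mutant reads
#'     within 5 bp of a read end is reported as a diagnostic;
#'   \item tumor-vs-normal allele counts differ significantly
#'     (two-sided Fisher exact, p < 0.05).
#' }
#' Variants missing the evidence vectors needed for a significance
#' criterion are rejected and tallied under `insufficient_evidence`.
#'
#' @param candidates a `candidate_variants()` table; all rows must have
#'   `variant_class == "SNV"`.
#' @param min_depth,min_tumor_vaf,max_normal_vaf,min_alt_reads,min_spacing
#'   numeric cutoffs for criteria I-IV (defaults as listed above).
#' @param mapq_threshold,p_mapq criterion V threshold and p cutoff.
#' @param baseq_threshold,p_baseq criterion VI threshold and p cutoff.
#' @param p_end criterion VII p cutoff.
#' @param p_fisher criterion VIII p cutoff.
#' @param zero_method zero-difference handling for the signed-rank tests.
#' @return a list with `passed` (the passing subset, with an added
#'   `end_prox_frac` diagnostic column) and `report` (a `filter_report`
#'   with `n_input`, `n_passed` and per-criterion rejection tallies;
#'   a variant may be tallied under several criteria).
#' @export
filter_snvs <- function(candidates,
                        min_depth = 10, min_tumor_vaf = 0.05,
                        max_normal_vaf = 0.02, min_alt_reads = 3,
                        min_spacing = 10,
                        mapq_threshold = 30, p_mapq = 0.2,
                        baseq_threshold = 20, p_baseq = 0.05,
                        p_end = 0.1, p_fisher = 0.05,
                        zero_method = "wilcox") {
  candidates <- candidate_variants(candidates)
  if (any(candidates$variant_class != "SNV")) {
    stopf("filter_snvs expects SNV candidates only; use filter_indels for indels")
  }
  n <- nrow(candidates)
  crit_labels <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
                   "insufficient_evidence")
  rejections <- stats::setNames(integer(length(crit_labels)), crit_labels)
  if (n == 0) {
    return(list(passed = candidates,
                report = filter_report(0L, 0L, rejections)))
  }

  fail <- matrix(FALSE, n, length(crit_labels),
                 dimnames = list(NULL, crit_labels))
  tvaf <- candidates$tumor_alt_count / pmax(candidates$tumor_depth, 1)
  nvaf <- candidates$normal_alt_count / pmax(candidates$normal_depth, 1)

  fail[, "I"] <- candidates$tumor_depth < min_depth |
    candidates$normal_depth < min_depth
  fail[, "II"] <- tvaf < min_tumor_vaf | nvaf >= max_normal_vaf
  fail[, "III"] <- candidates$tumor_alt_count < min_alt_reads

  # IV: pairwise spacing within chromosome; adjacent sorted positions
  # within min_spacing fail on both sides.
  for (chr in unique(candidates$chrom)) {
    idx <- which(candidates$chrom == chr)
    if (length(idx) < 2) next
    pos <- candidates$pos[idx]
    ord <- order(pos)
    d <- diff(pos[ord])
    close_pair <- which(d <= min_spacing)
    bad <- unique(c(ord[close_pair], ord[close_pair + 1]))
    fail[idx[bad], "IV"] <- TRUE
  }

  end_prox_frac <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    mq <- candidates$mutant_mapqs[[i]]
    bq <- candidates$mutant_baseqs[[i]]
    me <- candidates$mutant_end_distances[[i]]
    re <- candidates$ref_end_distances[[i]]
    if (!evidence_ok(mq) || !evidence_ok(bq) || !evidence_ok(me) ||
        !evidence_ok(re)) {
      fail[i, "insufficient_evidence"] <- TRUE
      next
    }
    fail[i, "V"] <- rank_test_vs_threshold(mq, mapq_threshold,
                                           zero_method = zero_method) >= p_mapq
    fail[i, "VI"] <- rank_test_vs_threshold(bq, baseq_threshold,
                                            zero_method = zero_method) >= p_baseq
    # VII: reject if mutant-supporting reads sit significantly nearer the
    # read ends than reference-supporting reads.
    p_vii <- suppressWarnings(
      stats::wilcox.test(me, re, alternative = "less")$p.value)
    fail[i, "VII"] <- p_vii < p_end
    end_prox_frac[i] <- mean(me <= 5)
  }

  for (i in seq_len(n)) {
    tab <- matrix(c(candidates$tumor_alt_count[i],
                    candidates$tumor_depth[i] - candidates$tumor_alt_count[i],
                    candidates$normal_alt_count[i],
                    candidates$normal_depth[i] - candidates$normal_alt_count[i]),
                  nrow = 2, byrow = TRUE)
    p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1
         else stats::fisher.test(tab)$p.value
    fail[i, "VIII"] <- p >= p_fisher
  }

  rejections[] <- colSums(fail)
  ok <- rowSums(fail) == 0
  passed <- candidates[ok, , drop = FALSE]
  passed$end_prox_frac <- end_prox_frac[ok]
  rownames(passed) <- NULL
  list(passed = passed,
       report = filter_report(n, sum(ok), rejections))
}

#' Filter candidate somatic InDels
#'
#' An indel passes if its tumor VAF is at least `min_vaf` (default 10\%)
#' and it is not flagged as a germline event.
#'
#' @param candidates a `candidate_variants()` table of insertions and
#'   deletions, with a logical `germline_flag` column.
#' @param min_vaf minimum tumor VAF to keep (boundary included).
#' @return a list with `passed` and `report`, as in [filter_snvs()];
#'   rejection labels are `indel_vaf` and `indel_germline`.
#' @export
filter_indels <- function(candidates, min_vaf = 0.10) {
  candidates <- candidate_variants(candidates)
  if (any(!candidates$variant_class %in% c("insertion", "deletion"))) {
    stopf("filter_indels expects insertion/deletion candidates only")
  }
  if (!"germline_flag" %in% names(candidates)) {
    stopf("indel candidates require a germline_flag column")
  }
  n <- nrow(candidates)
  vaf <- candidates$tumor_alt_count / pmax(candidates$tumor_depth, 1)
  fail_vaf <- vaf < min_vaf
  fail_germ <- as.logical(candidates$germline_flag)
  ok <- !fail_vaf & !fail_germ
  rejections <- c(indel_vaf = sum(fail_vaf), indel_germline = sum(fail_germ))
  passed <- candidates[ok, , drop = FALSE]
  rownames(passed) <- NULL
  list(passed = passed,
       report = filter_report(n, sum(ok), rejections))
}

filter_report <- function(n_input, n_passed, rejections) {
  structure(list(n_input = as.integer(n_input),
                 n_passed = as.integer(n_passed),
                 rejections = rejections),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Somatic variant filter: %d of %d candidates passed\n",
              x$n_passed, x$n_input))
  rej <- x$rejections[x$rejections > 0]
  if (length(rej)) {
    cat("Rejections by criterion (a variant may fail several):\n")
    for (nm in names(rej)) cat(sprintf("  %-22s %d\n", nm, rej[[nm]]))
  }
  invisible(x)
}
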