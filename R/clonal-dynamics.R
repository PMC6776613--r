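#' Exact binomial allele-frequency shift test
#'
#' Tests whether an observed alternate-read count is compatible with a fixed
#' null allele frequency `p0` — the workhorse for detecting per-variant MAF
#' shifts between matched samples.  The default two-sided p-value uses the
#' minimum-likelihood rule: the sum of binomial point probabilities of every
#' outcome no more likely than the observed one (the convention of
#' `binom.test`).  A central (doubled smaller tail, capped at 1) alternative
#' is available since two-sided conventions differ between tools.
#'
#' @param alt observed alternate-read count(s), `0 <= alt <= depth`.
#' @param depth total read depth(s), `>= 1`.
#' @param p0 null allele frequency, strictly inside (0, 1).
#' @param method `"minlike"` (default) or `"central"`.
#' @return vector of two-sided p-values.
#' @examples
#' binomialShiftTest(0, 20, 0.5)   # 2 * 0.5^20
#' binomialShiftTest(5, 10, 0.5)   # 1: modal outcome
#' @export
binomialShiftTest <- function(alt, depth, p0, method = c("minlike", "central")) {
  method <- match.arg(method)
  n <- max(length(alt), length(depth), length(p0))
  alt <- rep_len(alt, n); depth <- rep_len(depth, n); p0 <- rep_len(p0, n)
  if (any(p0 <= 0 | p0 >= 1))
    stop("p0 must lie strictly inside (0, 1)")
  if (any(depth < 1) || any(alt < 0) || any(alt > depth))
    stop("need 0 <= alt <= depth and depth >= 1")
  vapply(seq_len(n), function(i) {
    d <- dbinom(0:depth[i], depth[i], p0[i])
    if (method == "minlike") {
      # relative tolerance absorbs floating-point ties in point probabilities
      min(1, sum(d[d <= d[alt[i] + 1L] * (1 + 1e-7)]))
    } else {
      lo <- pbinom(alt[i], depth[i], p0[i])
      hi <- pbinom(alt[i] - 1L, depth[i], p0[i], lower.tail = FALSE)
      min(1, 2 * min(lo, hi))
    }
  }, numeric(1))
}

#' Multiple-testing adjustment of p-values
#'
#' Thin wrapper over [stats::p.adjust()] restricted to the two corrections
#' used for enriched-mutation calling: family-wise Bonferroni and
#' Benjamini-Hochberg false-discovery rate.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param method `"bonferroni"` (default) or `"bh"`.
#' @return adjusted p-values, same order as input.
#' @export
adjustPvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Per-variant allele-frequency shift tests between matched samples
#'
#' For every variant shared between samples `a` (reference timepoint, e.g.
#' PRE-treatment) and `b` (e.g. POST-treatment) that reaches `min_depth` in
#' both, tests the `b` read counts against the null allele frequency
#' observed in `a` (`p0 = maf_a`) with [binomialShiftTest()], adjusts the
#' p-values across the tested set, and classifies each variant as enriched
#' in `A` (frequency fell), enriched in `B` (frequency rose), or neither.
#' These are the "enriched mutations": shared variants whose MAF shift
#' survives multiple-testing correction, read as subclone expansion or
#' contraction under treatment selection.
#'
#' By default only coding and splice-site variants (effect classes
#' synonymous, nonsynonymous, splice) are tested, the set most likely to
#' carry a functional impact; disable `restrict_coding_splice` for germline
#' comparisons.  Variants whose reference MAF is exactly 0 or 1 cannot serve
#' as a binomial null and are excluded with a message.
#'
#' @param a,b [SampleVariants-class] objects; `a` supplies the null MAF.
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @param method correction passed to [adjustPvalues()] (default
#'   `"bonferroni"`).
#' @param min_depth per-sample minimum depth for a variant to be tested.
#' @param restrict_coding_splice keep only coding/splice effect classes
#'   (default TRUE).
#' @param test_method two-sided convention for [binomialShiftTest()].
#' @return data.frame with one row per tested variant: key columns,
#'   `effect_class`, `maf_a`, `maf_b`, `alt_b`, `depth_b`, `p_raw`, `p_adj`,
#'   `direction` (`up_in_b` / `down_in_b` / `none`), `enriched_in`
#'   (`A` / `B` / `none`).  Attributes record `alpha`, `method`, the
#'   reference sample, and the count of untestable variants.
#' @seealso [summarizeEnrichment()], [nsRatio()]
#' @export
comparePaired <- function(a, b, alpha = 0.05,
                          method = c("bonferroni", "bh"),
                          min_depth = 10, restrict_coding_splice = TRUE,
                          test_method = c("minlike", "central")) {
  method <- match.arg(method)
  test_method <- match.arg(test_method)
  stopifnot(is(a, "SampleVariants"), is(b, "SampleVariants"),
            alpha > 0, alpha < 1)
  ca <- variantCalls(a)
  cb <- variantCalls(b)
  ca$depth <- ca$ref_count + ca$alt_count
  cb$depth <- cb$ref_count + cb$alt_count
  ka <- .keyString(ca)
  kb <- .keyString(cb)
  idx_b <- match(ka, kb)
  shared <- !is.na(idx_b)
  empty <- data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), effect_class = character(), maf_a = numeric(),
    maf_b = numeric(), alt_b = integer(), depth_b = integer(),
    p_raw = numeric(), p_adj = numeric(), direction = character(),
    enriched_in = character(), stringsAsFactors = FALSE)
  res <- data.frame(
    chrom = ca$chrom[shared], pos = ca$pos[shared], ref = ca$ref[shared],
    alt = ca$alt[shared], effect_class = ca$effect_class[shared],
    maf_a = ca$maf[shared], maf_b = cb$maf[idx_b[shared]],
    alt_b = cb$alt_count[idx_b[shared]], depth_b = cb$depth[idx_b[shared]],
    depth_a = ca$depth[shared], stringsAsFactors = FALSE)
  res <- res[res$depth_a >= min_depth & res$depth_b >= min_depth, ,
             drop = FALSE]
  if (restrict_coding_splice)
    res <- res[res$effect_class %in% c("synonymous", "nonsynonymous",
                                       "splice"), , drop = FALSE]
  untestable <- res$maf_a <= 0 | res$maf_a >= 1
  n_untestable <- sum(untestable)
  if (n_untestable > 0L) {
    message(n_untestable,
            " shared variant(s) with reference MAF 0 or 1 excluded from testing")
    res <- res[!untestable, , drop = FALSE]
  }
  if (nrow(res) == 0L) {
    out <- empty
  } else {
    res$p_raw <- binomialShiftTest(res$alt_b, res$depth_b, res$maf_a,
                                   method = test_method)
    res$p_adj <- adjustPvalues(res$p_raw, method = method)
    delta <- res$maf_b - res$maf_a
    res$direction <- ifelse(delta > 0, "up_in_b",
                            ifelse(delta < 0, "down_in_b", "none"))
    res$enriched_in <- ifelse(res$p_adj < alpha & delta > 0, "B",
                              ifelse(res$p_adj < alpha & delta < 0, "A",
                                     "none"))
    res$depth_a <- NULL
    rownames(res) <- NULL
    out <- res
  }
  attr(out, "alpha") <- alpha
  attr(out, "method") <- method
  attr(out, "reference_sample") <- sampleId(a)
  attr(out, "n_untestable") <- n_untestable
  out
}

#' Nonsynonymous/synonymous ratio among enriched variants
#'
#' An N/S ratio above the neutral expectation among variants enriched on one
#' side suggests selection acting on protein-altering changes.
#'
#' @param comparisons data.frame from [comparePaired()].
#' @param side `"A"` or `"B"`: which side's enriched variants to count.
#' @return the ratio, or `NA` when no synonymous variant is enriched on that
#'   side (ratio undefined).
#' @export
nsRatio <- function(comparisons, side = c("B", "A")) {
  side <- match.arg(side)
  sub <- comparisons[comparisons$enriched_in == side, , drop = FALSE]
  n_non <- sum(sub$effect_class == "nonsynonymous")
  n_syn <- sum(sub$effect_class == "synonymous")
  if (n_syn == 0L) return(NA_real_)
  n_non / n_syn
}

#' Fisher's exact test on a 2x2 count table
#'
#' @param tab 2x2 matrix of non-negative integer counts with at least one
#'   positive entry.
#' @param alternative two-sided by default; one-sided options follow
#'   [stats::fisher.test()] conventions on the odds ratio of the table as
#'   given.
#' @return list with elements `p`, `odds` (conditional MLE odds ratio; may
#'   be `Inf`), and the input table.
#' @examples
#' fisher2x2(matrix(c(136, 8, 46, 5), nrow = 2))
#' @export
fisher2x2 <- function(tab, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("cells must be non-negative integers")
  if (sum(tab) == 0)
    stop("all-zero table has no defined test")
  ft <- fisher.test(tab, alternative = alternative)
  list(p = ft$p.value, odds = unname(ft$estimate), table = tab)
}

#' MAF concordance between matched samples
#'
#' Pearson correlation of mutant-allele frequencies over shared variants
#' passing the depth filter in both samples — high concordance (R^2 near 1)
#' indicates a stable clonal composition between the two samples.
#'
#' @param a,b [SampleVariants-class] objects.
#' @param min_depth per-sample minimum depth (default 10).
#' @return list with `r`, `r2`, `n`; `r`/`r2` are `NA` when fewer than 3
#'   shared variants remain.
#' @export
mafConcordance <- function(a, b, min_depth = 10) {
  stopifnot(is(a, "SampleVariants"), is(b, "SampleVariants"))
  ca <- variantCalls(a)
  cb <- variantCalls(b)
  idx <- match(.keyString(ca), .keyString(cb))
  ok <- !is.na(idx) &
    (ca$ref_count + ca$alt_count) >= min_depth &
    (cb$ref_count[idx] + cb$alt_count[idx]) >= min_depth
  x <- ca$maf[ok]
  y <- cb$maf[idx[ok]]
  if (length(x) < 3L)
    return(list(r = NA_real_, r2 = NA_real_, n = length(x)))
  r <- cor(x, y)
  list(r = r, r2 = r^2, n = length(x))
}

#' Cohort-level summary of enriched mutations
#'
#' Aggregates a paired-comparison table into the headline numbers of a
#' subclonal-dynamics analysis: how many shared variants were tested, how
#' many were enriched on each side (with one-decimal percentage
#' presentation), side-specific N/S ratios, and a Fisher exact contrast of
#' the N/S composition between sides.
#'
#' @param comparisons data.frame from [comparePaired()].
#' @param alternative sidedness for the N/S Fisher contrast (default
#'   two-sided).
#' @return object of class `itgh_enrichment`: list with `n_shared_tested`,
#'   `n_enriched`, `n_enriched_a`, `n_enriched_b`, `frac_enriched`,
#'   `frac_a`, `frac_b` (fractions of `n_enriched`), `ns_ratio_a`,
#'   `ns_ratio_b`, `fisher_p`, `fisher_odds`, `ns_table`.
#' @export
summarizeEnrichment <- function(comparisons,
                                alternative = c("two.sided", "greater",
                                                "less")) {
  alternative <- match.arg(alternative)
  n_tested <- nrow(comparisons)
  n_a <- sum(comparisons$enriched_in == "A")
  n_b <- sum(comparisons$enriched_in == "B")
  n_enr <- n_a + n_b
  ns_tab <- matrix(c(
    sum(comparisons$enriched_in == "B" &
          comparisons$effect_class == "nonsynonymous"),
    sum(comparisons$enriched_in == "A" &
          comparisons$effect_class == "nonsynonymous"),
    sum(comparisons$enriched_in == "B" &
          comparisons$effect_class == "synonymous"),
    sum(comparisons$enriched_in == "A" &
          comparisons$effect_class == "synonymous")),
    nrow = 2L, dimnames = list(side = c("B", "A"),
                               class = c("nonsynonymous", "synonymous")))
  fisher <- if (sum(ns_tab) > 0 && all(rowSums(ns_tab) > 0))
    fisher2x2(ns_tab, alternative = alternative)
  else list(p = NA_real_, odds = NA_real_)
  structure(list(
    n_shared_tested = n_tested,
    n_enriched = n_enr, n_enriched_a = n_a, n_enriched_b = n_b,
    frac_enriched = if (n_tested > 0) n_enr / n_tested else NA_real_,
    frac_a = if (n_enr > 0) n_a / n_enr else NA_real_,
    frac_b = if (n_enr > 0) n_b / n_enr else NA_real_,
    ns_ratio_a = nsRatio(comparisons, "A"),
    ns_ratio_b = nsRatio(comparisons, "B"),
    fisher_p = fisher$p, fisher_odds = fisher$odds,
    ns_table = ns_tab
  ), class = "itgh_enrichment")
}

#' @export
print.itgh_enrichment <- function(x, ...) {
  cat("Enrichment summary\n")
  cat(sprintf("  tested shared variants: %d\n", x$n_shared_tested))
  if (x$n_enriched > 0) {
    cat(sprintf("  enriched: %d (%.1f%%)  [A: %d (%.1f%%)  B: %d (%.1f%%)]\n",
                x$n_enriched, 100 * x$frac_enriched,
                x$n_enriched_a, 100 * x$frac_a,
                x$n_enriched_b, 100 * x$frac_b))
  } else {
    cat("  enriched: 0\n")
  }
  cat(sprintf("  N/S ratio A: %s   B: %s\n",
              ifelse(is.na(x$ns_ratio_a), "unavailable",
                     sprintf("%.2f", x$ns_ratio_a)),
              ifelse(is.na(x$ns_ratio_b), "unavailable",
                     sprintf("%.2f", x$ns_ratio_b))))
  if (!is.na(x$fisher_p))
    cat(sprintf("  N/S-by-side Fisher: p = %.3g, odds = %.3g\n",
                x$fisher_p, x$fisher_odds))
  invisible(x)
}
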