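#' Extract depth-filtered mutant-allele frequencies
#'
#' Returns one MAF per observation whose total read depth
#' (`ref_count + alt_count`) reaches `min_depth`, preserving input order.
#' Depth filtering stabilizes the MAF distribution before dispersion
#' statistics are taken from it.
#'
#' @param x a [SampleVariants-class] object.
#' @param min_depth minimum total depth (default 10).
#' @return numeric vector of MAFs (possibly empty).
#' @export
extractMafs <- function(x, min_depth = 10) {
  stopifnot(is(x, "SampleVariants"), min_depth >= 1)
  calls <- variantCalls(x)
  depth <- calls$ref_count + calls$alt_count
  calls$maf[depth >= min_depth]
}

#' MATH score of a MAF distribution
#'
#' The MATH (mutant-allele tumor heterogeneity) score quantifies
#' intratumoral genetic heterogeneity as the width of a sample's MAF
#' distribution relative to its center:
#' \deqn{\mathrm{MATH} = 100 \times \mathrm{MAD}(\mathrm{MAF}) /
#'   \mathrm{median}(\mathrm{MAF})}
#' where MAD is the median absolute deviation scaled by the
#' normal-consistency constant 1.4826.  Heterogeneous tumors harbor
#' subclones at distinct cancer-cell fractions, broadening the MAF
#' distribution and raising the score; because tumor purity rescales all
#' MAFs jointly, the ratio is first-order insensitive to normal-cell
#' contamination.
#'
#' Samples with fewer than `min_variants` usable MAFs, or a zero median, get
#' a flagged result (`math_score = NA`) rather than an error, so cohort
#' tables retain every sample.
#'
#' @param x numeric vector of MAFs in `[0, 1]`.
#' @param min_variants minimum number of MAFs for a defined score
#'   (default 5).
#' @param sample_id optional identifier carried into the result row.
#' @return one-row data.frame with columns `sample_id`, `n_variants`,
#'   `median_maf`, `mad`, `math_score`, `flag` (`"ok"`,
#'   `"too_few_variants"`, or `"zero_median"`).
#' @examples
#' mathScore(c(0.1, 0.2, 0.3), min_variants = 3)  # 74.13
#' @export
mathScore <- function(x, min_variants = 5, sample_id = NA_character_) {
  x <- x[!is.na(x)]
  n <- length(x)
  res <- data.frame(sample_id = sample_id, n_variants = n,
                    median_maf = NA_real_, mad = NA_real_,
                    math_score = NA_real_, flag = "ok",
                    stringsAsFactors = FALSE)
  if (n < min_variants) {
    res$flag <- "too_few_variants"
    return(res)
  }
  med <- median(x)
  res$median_maf <- med
  res$mad <- mad(x, center = med, constant = 1.4826)
  if (med == 0) {
    res$flag <- "zero_median"
    return(res)
  }
  res$math_score <- 100 * res$mad / med
  res
}

#' Per-sample MATH scores for a cohort
#'
#' Applies [extractMafs()] and [mathScore()] to every sample and returns one
#' row per sample; flagged samples (too few variants, zero median) are
#' retained with `math_score = NA`.  Cohort summary statistics over the
#' available scores are attached as attribute `"summary"` and also returned
#' by [mathSummary()].
#'
#' @param tables list of [SampleVariants-class] objects.
#' @param min_depth per-variant minimum depth (default 10).
#' @param min_variants minimum MAF count per sample (default 5).
#' @return data.frame of MATH results (see [mathScore()]) with a `"summary"`
#'   attribute.
#' @export
cohortMath <- function(tables, min_depth = 10, min_variants = 5) {
  stopifnot(is.list(tables))
  rows <- lapply(tables, function(tab) {
    mathScore(extractMafs(tab, min_depth = min_depth),
              min_variants = min_variants, sample_id = sampleId(tab))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- mathScore(numeric(0))[0, ]
  attr(out, "summary") <- mathSummary(out)
  out
}

#' Summary statistics over available MATH scores
#'
#' @param scores data.frame from [cohortMath()] (or any table with a
#'   `math_score` column).
#' @return named numeric vector: `n_available`, `median`, `mean`, `q1`,
#'   `q3`, `min`, `max`; all `NA` (except the count) when no sample has an
#'   available score.
#' @export
mathSummary <- function(scores) {
  s <- scores$math_score
  s <- s[!is.na(s)]
  if (length(s) == 0L)
    return(c(n_available = 0, median = NA_real_, mean = NA_real_,
             q1 = NA_real_, q3 = NA_real_, min = NA_real_, max = NA_real_))
  c(n_available = length(s), median = median(s), mean = mean(s),
    q1 = unname(quantile(s, 0.25)), q3 = unname(quantile(s, 0.75)),
    min = min(s), max = max(s))
}
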