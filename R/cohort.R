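#' Two-group comparison of score distributions
#'
#' Rank-based comparison of two groups of scores (typically MATH scores
#' across clinical strata).  Unpaired groups use the two-sided Wilcoxon
#' rank-sum test, exact when both groups have at most 25 observations and
#' the pooled values carry no ties, otherwise the normal approximation with
#' continuity correction.  Paired groups use the Wilcoxon signed-rank test
#' on the non-zero differences under the same exact/approximate rule; when
#' every difference is zero the comparison is degenerate and reported with
#' p = 1.
#'
#' @param values_a,values_b numeric score vectors (equal length when
#'   paired).
#' @param paired within-subject comparison (default FALSE).
#' @param labels length-2 character vector naming the groups.
#' @return object of class `itgh_group_comparison`: list with
#'   `group_labels`, `n_per_group`, `medians`, `statistic`, `p`, `paired`,
#'   `exact`, `degenerate`.
#' @examples
#' compareGroups(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
compareGroups <- function(values_a, values_b, paired = FALSE,
                          labels = c("A", "B")) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  na <- length(values_a); nb <- length(values_b)
  if (paired && na != nb)
    stop("paired comparison requires equal group lengths")
  if (na < 1L || nb < 1L)
    stop("each group needs at least one value")
  degenerate <- FALSE
  if (paired) {
    d <- values_b - values_a
    nz <- d[d != 0]
    if (length(nz) == 0L) {
      res <- list(statistic = NA_real_, p.value = 1)
      exact <- TRUE
      degenerate <- TRUE
    } else {
      exact <- length(nz) <= 25L && !anyDuplicated(abs(nz))
      res <- suppressWarnings(
        wilcox.test(values_a, values_b, paired = TRUE, exact = exact,
                    correct = TRUE))
    }
  } else {
    pooled <- c(values_a, values_b)
    exact <- na <= 25L && nb <= 25L && !anyDuplicated(pooled)
    res <- suppressWarnings(
      wilcox.test(values_a, values_b, exact = exact, correct = TRUE))
  }
  structure(list(
    group_labels = labels,
    n_per_group = c(na, nb),
    medians = c(median(values_a), median(values_b)),
    statistic = unname(if (is.list(res)) res$statistic else NA_real_),
    p = res$p.value,
    paired = paired, exact = exact, degenerate = degenerate
  ), class = "itgh_group_comparison")
}

#' @export
print.itgh_group_comparison <- function(x, ...) {
  cat(sprintf("%s Wilcoxon %s test%s\n",
              if (x$paired) "Paired" else "Unpaired",
              if (x$paired) "signed-rank" else "rank-sum",
              if (x$exact) " (exact)" else " (normal approx.)"))
  cat(sprintf("  %s: n = %d, median = %.4g\n", x$group_labels[1],
              x$n_per_group[1], x$medians[1]))
  cat(sprintf("  %s: n = %d, median = %.4g\n", x$group_labels[2],
              x$n_per_group[2], x$medians[2]))
  cat(sprintf("  p = %.4g%s\n", x$p,
              if (x$degenerate) " (degenerate: all differences zero)" else ""))
  invisible(x)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y equal-length numeric vectors (n >= 3), neither constant.
#' @return list with `r`, `p`, `n`; when a vector is constant or too short,
#'   `r`/`p` are `NA` and `reason` says why.
#' @export
correlate <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L)
    return(list(r = NA_real_, p = NA_real_, n = n,
                reason = "fewer than 3 complete pairs"))
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(r = NA_real_, p = NA_real_, n = n,
                reason = "constant vector"))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Associate MATH scores with clinical groupings and covariates
#'
#' Runs the cohort-level battery on a MATH score table: disease stage
#' (I+II vs III+IV) and nodal status (N0 vs N1+N2) by unpaired Wilcoxon
#' rank-sum, and copy-number burden and tumor purity by Pearson
#' correlation.  Note the nodal contrast across independent patients is
#' necessarily unpaired; the paired signed-rank test is reserved for
#' within-patient PRE/POST contrasts (use [compareGroups()] with
#' `paired = TRUE` directly).  A test whose metadata column is absent or
#' entirely missing is reported as skipped with the reason, never dropped
#' silently.
#'
#' @param math_table data.frame from [cohortMath()] (needs `sample_id`,
#'   `math_score`).
#' @param metadata data.frame keyed by `sample_id` with any of `stage`
#'   (I/II/III/IV), `nodal` (N0/N1/N2), `cnv_count`, `purity`.
#' @param alpha significance level echoed in the report (default 0.05).
#' @return object of class `itgh_math_report`: list with elements `stage`,
#'   `nodal` (group comparisons), `cnv`, `purity` (correlations), each
#'   either a result or `list(skipped = reason)`, plus `n_samples` and
#'   `alpha`.
#' @export
associateMath <- function(math_table, metadata, alpha = 0.05) {
  stopifnot(is.data.frame(math_table), is.data.frame(metadata))
  if (!"sample_id" %in% names(metadata))
    stop("metadata must carry a sample_id column")
  merged <- merge(math_table, metadata, by = "sample_id")
  merged <- merged[!is.na(merged$math_score), , drop = FALSE]
  if (nrow(merged) == 0L)
    stop("no overlapping sample ids between MATH table and metadata")

  group_test <- function(col, lo_levels, hi_levels, labels) {
    if (!col %in% names(merged))
      return(list(skipped = paste0("column '", col, "' absent")))
    g <- as.character(merged[[col]])
    lo <- merged$math_score[g %in% lo_levels]
    hi <- merged$math_score[g %in% hi_levels]
    if (length(lo) < 1L || length(hi) < 1L)
      return(list(skipped = paste0("a '", col, "' group is empty")))
    compareGroups(lo, hi, paired = FALSE, labels = labels)
  }
  cor_test <- function(col) {
    if (!col %in% names(merged))
      return(list(skipped = paste0("column '", col, "' absent")))
    res <- correlate(merged$math_score, as.numeric(merged[[col]]))
    if (!is.null(res$reason)) list(skipped = res$reason) else res
  }

  structure(list(
    n_samples = nrow(merged),
    alpha = alpha,
    stage = group_test("stage", c("I", "II"), c("III", "IV"),
                       c("stage I/II", "stage III/IV")),
    nodal = group_test("nodal", "N0", c("N1", "N2"),
                       c("N0", "N1+N2")),
    cnv = cor_test("cnv_count"),
    purity = cor_test("purity"),
    note = paste("group contrasts across independent patients use the",
                 "unpaired rank-sum test; paired signed-rank is reserved",
                 "for within-patient timepoint contrasts")
  ), class = "itgh_math_report")
}

#' @export
print.itgh_math_report <- function(x, ...) {
  cat("MATH association report (", x$n_samples, " samples)\n", sep = "")
  for (name in c("stage", "nodal")) {
    el <- x[[name]]
    cat("-- ", name, ": ", sep = "")
    if (!is.null(el$skipped)) {
      cat("skipped: ", el$skipped, "\n", sep = "")
    } else {
      cat(sprintf("%s median %.4g (n=%d) vs %s median %.4g (n=%d), p = %.3g\n",
                  el$group_labels[1], el$medians[1], el$n_per_group[1],
                  el$group_labels[2], el$medians[2], el$n_per_group[2],
                  el$p))
    }
  }
  for (name in c("cnv", "purity")) {
    el <- x[[name]]
    cat("-- ", name, ": ", sep = "")
    if (!is.null(el$skipped))
      cat("skipped: ", el$skipped, "\n", sep = "")
    else
      cat(sprintf("Pearson r = %.3g, p = %.3g (n = %d)\n", el$r, el$p, el$n))
  }
  invisible(x)
}
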