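#' @include SampleVariants-class.R
NULL

.TSV_HEADER <- c("sample_id", "chrom", "pos", "ref", "alt",
                 "ref_count", "alt_count", "effect_class")

.isSnvAllele <- function(x) x %in% .BASES

.stripChr <- function(chrom, strip) {
  if (strip) sub("^chr", "", chrom) else chrom
}

#' Read somatic SNVs for one sample from a VCF file
#'
#' Extracts biallelic SNV observations for the named sample column from a
#' VCF 4.x file.  Allele counts come from the per-sample `AD` FORMAT field
#' (ref, alt, ...); the total depth is the sum of the `AD` entries.
#' Multi-allelic records are split into one observation per single-base
#' alternate allele (non-SNV alleles are dropped); indels and MNVs are
#' dropped entirely.  Records without a parseable `AD` are skipped with a
#' warning, since no mutant-allele frequency can be derived from `DP` alone.
#'
#' @param path VCF file (plain or bgzipped).
#' @param sample_id sample column to extract.
#' @param strip_chr_prefix drop a leading `"chr"` from chromosome names.
#' @return a [SampleVariants-class] object (effect classes are `"unknown"`,
#'   as VCF carries no standardized consequence field).
#' @export
readVariantVcf <- function(path, sample_id, strip_chr_prefix = FALSE) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt_samples <- colnames(vcf@gt)[-1L]
  if (!sample_id %in% gt_samples)
    stop("sample '", sample_id, "' not present in VCF (has: ",
         paste(gt_samples, collapse = ", "), ")")
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  out <- vector("list", n)
  n_skipped <- 0L
  if (n > 0L) {
    ad <- vcfR::extract.gt(vcf, element = "AD")[, sample_id]
    for (i in seq_len(n)) {
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
      ref <- toupper(fix$REF[i])
      if (!.isSnvAllele(ref)) next          # indel/MNV reference
      ad_i <- suppressWarnings(
        as.integer(strsplit(ifelse(is.na(ad[i]), "", ad[i]),
                            ",", fixed = TRUE)[[1]]))
      if (length(ad_i) != length(alts) + 1L || anyNA(ad_i)) {
        n_skipped <- n_skipped + 1L
        next
      }
      total <- sum(ad_i)
      keep <- .isSnvAllele(toupper(alts))
      if (!any(keep)) next
      alt_counts <- ad_i[-1L][keep]
      out[[i]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = ref, alt = toupper(alts[keep]),
        ref_count = total - alt_counts, alt_count = alt_counts,
        effect_class = "unknown", stringsAsFactors = FALSE)
    }
  }
  if (n_skipped > 0L)
    warning(n_skipped, " VCF record(s) without parseable allele depths skipped")
  calls <- do.call(rbind, out)
  if (is.null(calls))
    calls <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        ref_count = integer(), alt_count = integer(),
                        effect_class = character(), stringsAsFactors = FALSE)
  calls$chrom <- .stripChr(calls$chrom, strip_chr_prefix)
  calls <- .collapseDuplicateKeys(.canonicalCalls(calls), sample_id)
  SampleVariants(sample_id, calls)
}

.MAF_REQUIRED <- c("Chromosome", "Start_Position", "Reference_Allele",
                   "Tumor_Seq_Allele2", "Tumor_Sample_Barcode",
                   "t_ref_count", "t_alt_count")

.VARIANT_CLASS_MAP <- c(
  Silent            = "synonymous",
  Missense_Mutation = "nonsynonymous",
  Nonsense_Mutation = "nonsynonymous",
  Nonstop_Mutation  = "nonsynonymous",
  Splice_Site       = "splice"
)

#' Read a TCGA-style MAF (Mutation Annotation Format) table
#'
#' Parses a tab-separated mutation table in the TCGA MAF dialect and groups
#' rows by `Tumor_Sample_Barcode` into one [SampleVariants-class] per sample.
#' `Variant_Classification` is collapsed onto the package's effect classes
#' (Silent to synonymous; Missense/Nonsense/Nonstop to nonsynonymous;
#' Splice_Site to splice; anything else to other; column absent to unknown).
#' Rows with non-SNV alleles or missing read counts are dropped and counted
#' in a message.
#'
#' @param path MAF file; `#`-prefixed header comments are ignored.
#' @param strip_chr_prefix drop a leading `"chr"` from chromosome names.
#' @return named list of [SampleVariants-class], one per barcode, in order
#'   of first appearance.
#' @export
readMafCohort <- function(path, strip_chr_prefix = FALSE) {
  if (!file.exists(path)) stop("MAF file not found: ", path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing_cols <- setdiff(.MAF_REQUIRED, names(df))
  if (length(missing_cols))
    stop("MAF format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  has_vc <- "Variant_Classification" %in% names(df)
  ref <- toupper(as.character(df$Reference_Allele))
  alt <- toupper(as.character(df$Tumor_Seq_Allele2))
  rc <- suppressWarnings(as.integer(df$t_ref_count))
  ac <- suppressWarnings(as.integer(df$t_alt_count))
  ok <- .isSnvAllele(ref) & .isSnvAllele(alt) & ref != alt &
    !is.na(rc) & !is.na(ac)
  n_dropped <- sum(!ok)
  if (n_dropped > 0L)
    message(n_dropped, " MAF row(s) with non-SNV alleles or missing counts dropped")
  df <- df[ok, , drop = FALSE]
  ref <- ref[ok]; alt <- alt[ok]; rc <- rc[ok]; ac <- ac[ok]
  effect <- if (has_vc) {
    e <- unname(.VARIANT_CLASS_MAP[as.character(df$Variant_Classification)])
    ifelse(is.na(e), "other", e)
  } else rep("unknown", nrow(df))
  calls <- data.frame(
    chrom = .stripChr(as.character(df$Chromosome), strip_chr_prefix),
    pos = as.integer(df$Start_Position),
    ref = ref, alt = alt, ref_count = rc, alt_count = ac,
    effect_class = effect, stringsAsFactors = FALSE)
  barcodes <- as.character(df$Tumor_Sample_Barcode)
  out <- lapply(unique(barcodes), function(b) {
    sub <- .collapseDuplicateKeys(
      .canonicalCalls(calls[barcodes == b, , drop = FALSE]), b)
    SampleVariants(b, sub)
  })
  names(out) <- unique(barcodes)
  out
}

#' Read / write the plain variant TSV dialect
#'
#' The TSV dialect is tab-separated with header exactly
#' `sample_id, chrom, pos, ref, alt, ref_count, alt_count, effect_class`
#' and one row per SNV observation; a missing effect class is written as
#' `"unknown"`.  Lines starting with `#` are treated as provenance comments
#' and skipped on read.  `writeVariantTsv()` followed by `readVariantTsv()`
#' reproduces the observations exactly, and write-read-write is
#' byte-identical.
#'
#' @param path file path.
#' @param strip_chr_prefix drop a leading `"chr"` from chromosome names on
#'   read.
#' @return `readVariantTsv()`: a [SampleVariants-class]; the file must
#'   contain observations for a single sample.  `writeVariantTsv()`:
#'   the path, invisibly.
#' @export
readVariantTsv <- function(path, strip_chr_prefix = FALSE) {
  if (!file.exists(path)) stop("variant TSV not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#")
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) stop("variant TSV is empty: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
  if (!identical(header, .TSV_HEADER))
    stop("variant TSV header must be exactly: ",
         paste(.TSV_HEADER, collapse = ", "))
  body <- lines[-1L]
  body_no <- line_no[-1L]
  if (length(body) == 0L) {
    return(SampleVariants(NA_character_,
                          data.frame(chrom = character(), pos = integer(),
                                     ref = character(), alt = character(),
                                     ref_count = integer(),
                                     alt_count = integer(),
                                     effect_class = character(),
                                     stringsAsFactors = FALSE)))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != length(.TSV_HEADER))
  if (length(bad))
    stop("malformed variant TSV row at line ", body_no[bad[1L]],
         " of ", path)
  m <- do.call(rbind, parts)
  pos <- suppressWarnings(as.integer(m[, 3L]))
  rc <- suppressWarnings(as.integer(m[, 6L]))
  ac <- suppressWarnings(as.integer(m[, 7L]))
  bad <- which(is.na(pos) | is.na(rc) | is.na(ac) |
                 !.isSnvAllele(toupper(m[, 4L])) |
                 !.isSnvAllele(toupper(m[, 5L])))
  if (length(bad))
    stop("malformed variant TSV row at line ", body_no[bad[1L]],
         " of ", path)
  sample_ids <- unique(m[, 1L])
  if (length(sample_ids) != 1L)
    stop("variant TSV contains ", length(sample_ids),
         " sample ids; expected one (", paste(sample_ids, collapse = ", "), ")")
  calls <- data.frame(
    chrom = .stripChr(m[, 2L], strip_chr_prefix), pos = pos,
    ref = toupper(m[, 4L]), alt = toupper(m[, 5L]),
    ref_count = rc, alt_count = ac, effect_class = m[, 8L],
    stringsAsFactors = FALSE)
  calls <- .collapseDuplicateKeys(.canonicalCalls(calls), sample_ids)
  SampleVariants(sample_ids, calls)
}

#' @rdname readVariantTsv
#' @param x a [SampleVariants-class] object.
#' @param provenance optional comment string written as a leading `# ` line
#'   (used by the command-line wrapper for run provenance).
#' @export
writeVariantTsv <- function(x, path, provenance = NULL) {
  stopifnot(is(x, "SampleVariants"))
  calls <- variantCalls(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", provenance), con)
  writeLines(paste(.TSV_HEADER, collapse = "\t"), con)
  if (nrow(calls) > 0L) {
    ec <- ifelse(is.na(calls$effect_class) | calls$effect_class == "",
                 "unknown", calls$effect_class)
    writeLines(paste(sampleId(x), calls$chrom, calls$pos, calls$ref,
                     calls$alt, calls$ref_count, calls$alt_count, ec,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Partition two samples' variants into shared and private sets
#'
#' Compares variant keys (chrom, pos, ref, alt) between two samples with
#' exact equality and returns the shared keys and those private to either
#' side — the overlap structure used to ask how much of a tumor's mutation
#' complement survives treatment (or how concordant two germline samples
#' are).
#'
#' @param a,b [SampleVariants-class] objects.
#' @return an object of class `itgh_partition`: a list with key tables
#'   `shared`, `a_only`, `b_only`, the sample ids, and counts `n_a`, `n_b`,
#'   `n_union`.
#' @examples
#' a <- SampleVariants("a", data.frame(chrom = "1", pos = 1:3, ref = "A",
#'   alt = "T", ref_count = 50, alt_count = 50))
#' b <- SampleVariants("b", data.frame(chrom = "1", pos = 2:4, ref = "A",
#'   alt = "T", ref_count = 50, alt_count = 50))
#' partitionVariants(a, b)
#' @export
partitionVariants <- function(a, b) {
  stopifnot(is(a, "SampleVariants"), is(b, "SampleVariants"))
  ka <- variantKeys(a)
  kb <- variantKeys(b)
  sa <- .keyString(ka)
  sb <- .keyString(kb)
  out <- structure(list(
    shared  = ka[sa %in% sb, , drop = FALSE],
    a_only  = ka[!sa %in% sb, , drop = FALSE],
    b_only  = kb[!sb %in% sa, , drop = FALSE],
    sample_a = sampleId(a), sample_b = sampleId(b),
    n_a = nrow(ka), n_b = nrow(kb),
    n_union = length(union(sa, sb))
  ), class = "itgh_partition")
  rownames(out$shared) <- rownames(out$a_only) <- rownames(out$b_only) <- NULL
  out
}

#' Shared fraction of a variant partition
#'
#' @param part an `itgh_partition` from [partitionVariants()].
#' @param of denominator side: `"a"`, `"b"`, or `"union"`.
#' @return shared fraction in `[0, 1]` (`NaN` for an empty denominator).
#' @export
sharedFraction <- function(part, of = c("a", "b", "union")) {
  of <- match.arg(of)
  denom <- switch(of, a = part$n_a, b = part$n_b, union = part$n_union)
  nrow(part$shared) / denom
}

#' @export
print.itgh_partition <- function(x, ...) {
  cat(sprintf("Variant partition: %s vs %s\n", x$sample_a, x$sample_b))
  cat(sprintf("  shared: %d   %s-only: %d   %s-only: %d   union: %d\n",
              nrow(x$shared), x$sample_a, nrow(x$a_only),
              x$sample_b, nrow(x$b_only), x$n_union))
  if (x$n_a > 0)
    cat(sprintf("  shared of %s: %.1f%% (%d/%d)\n", x$sample_a,
                100 * nrow(x$shared) / x$n_a, nrow(x$shared), x$n_a))
  invisible(x)
}
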