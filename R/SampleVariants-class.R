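#' SampleVariants: somatic SNV observations for one sample
#'
#' S4 container holding all somatic single-nucleotide variant observations for
#' one sequenced sample, together with the clinical metadata used by the
#' cohort-level statistics.  Each row of the call table is one biallelic SNV
#' with per-variant read counts; the mutant-allele frequency (MAF) is derived
#' as `alt_count / (ref_count + alt_count)` and stored alongside.
#'
#' Variant identity is the 4-tuple (chrom, pos, ref, alt): 1-based, fully
#' closed coordinates as in VCF/MAF, single-base alleles only.  A sample never
#' contains the same key twice (readers resolve collisions by keeping the
#' deeper record).
#'
#' @slot sampleId single sample identifier.
#' @slot calls `data.frame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `ref_count`, `alt_count`, `effect_class`, `maf`.
#' @slot timepoint one of `"PRE"`, `"POST"`, `"BC"`, `"Nrx"`, `"NA"`.
#' @slot purity tumor cell fraction in `[0, 1]`, or `NA`.
#' @slot stage disease stage `"I"`..`"IV"`, or `"NA"`.
#' @slot nodal nodal status `"N0"`, `"N1"`, `"N2"`, or `"NA"`.
#' @slot cnvCount total somatic copy-number variant count, or `NA`.
#'
#' @aliases SampleVariants-class
#' @seealso [readVariantTsv()], [extractMafs()], [comparePaired()]
#' @export
setClass("SampleVariants",
  representation(
    sampleId  = "character",
    calls     = "data.frame",
    timepoint = "character",
    purity    = "numeric",
    stage     = "character",
    nodal     = "character",
    cnvCount  = "integer"
  ),
  prototype(
    sampleId  = NA_character_,
    timepoint = "NA",
    purity    = NA_real_,
    stage     = "NA",
    nodal     = "NA",
    cnvCount  = NA_integer_
  )
)

.CALL_COLUMNS <- c("chrom", "pos", "ref", "alt", "ref_count", "alt_count",
                   "effect_class", "maf")

setValidity("SampleVariants", function(object) {
  msgs <- character()
  calls <- object@calls
  if (length(object@sampleId) != 1L)
    msgs <- c(msgs, "sampleId must be a single string")
  if (!all(.CALL_COLUMNS %in% names(calls)))
    msgs <- c(msgs, paste0("calls must have columns: ",
                           paste(.CALL_COLUMNS, collapse = ", ")))
  else if (nrow(calls) > 0L) {
    if (any(calls$pos < 1L))
      msgs <- c(msgs, "positions must be >= 1 (1-based)")
    if (!all(calls$ref %in% .BASES) || !all(calls$alt %in% .BASES))
      msgs <- c(msgs, "ref and alt must be single bases in {A,C,G,T}")
    if (any(calls$ref == calls$alt))
      msgs <- c(msgs, "ref and alt must differ")
    if (any(calls$ref_count < 0L) || any(calls$alt_count < 0L))
      msgs <- c(msgs, "read counts must be non-negative")
    if (!all(calls$effect_class %in% .EFFECT_CLASSES))
      msgs <- c(msgs, paste0("effect_class must be one of: ",
                             paste(.EFFECT_CLASSES, collapse = ", ")))
    if (anyDuplicated(.keyString(calls)))
      msgs <- c(msgs, "duplicate variant keys within one sample")
    depth <- calls$ref_count + calls$alt_count
    ok <- depth > 0L
    if (any(ok & (calls$maf < 0 | calls$maf > 1), na.rm = TRUE))
      msgs <- c(msgs, "maf must lie in [0, 1]")
  }
  if (!object@timepoint %in% .TIMEPOINTS)
    msgs <- c(msgs, paste0("timepoint must be one of: ",
                           paste(.TIMEPOINTS, collapse = ", ")))
  if (!object@stage %in% .STAGES)
    msgs <- c(msgs, "stage must be I, II, III, IV or NA")
  if (!object@nodal %in% .NODALS)
    msgs <- c(msgs, "nodal must be N0, N1, N2 or NA")
  if (!is.na(object@purity) && (object@purity < 0 || object@purity > 1))
    msgs <- c(msgs, "purity must lie in [0, 1]")
  if (!is.na(object@cnvCount) && object@cnvCount < 0L)
    msgs <- c(msgs, "cnvCount must be non-negative")
  if (length(msgs)) msgs else TRUE
})

# canonical string form of the (chrom, pos, ref, alt) key
.keyString <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

# coerce a raw call data.frame into canonical column types and derive maf
.canonicalCalls <- function(df) {
  if (nrow(df) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      ref_count = integer(), alt_count = integer(),
                      effect_class = character(), maf = numeric(),
                      stringsAsFactors = FALSE))
  }
  depth <- as.integer(df$ref_count) + as.integer(df$alt_count)
  data.frame(
    chrom        = as.character(df$chrom),
    pos          = as.integer(df$pos),
    ref          = toupper(as.character(df$ref)),
    alt          = toupper(as.character(df$alt)),
    ref_count    = as.integer(df$ref_count),
    alt_count    = as.integer(df$alt_count),
    effect_class = if ("effect_class" %in% names(df))
                     as.character(df$effect_class) else "unknown",
    maf          = ifelse(depth > 0L, as.integer(df$alt_count) / depth,
                          NA_real_),
    row.names    = NULL, stringsAsFactors = FALSE
  )
}

# resolve duplicate keys: keep the record with the greater total depth
.collapseDuplicateKeys <- function(df, sample_id = "<sample>") {
  key <- .keyString(df)
  if (!anyDuplicated(key)) return(df)
  n_dup <- sum(duplicated(key))
  depth <- df$ref_count + df$alt_count
  ord <- order(key, -depth)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(.keyString(df)), , drop = FALSE]
  df <- df[order(df$chrom, df$pos, df$ref, df$alt), , drop = FALSE]
  rownames(df) <- NULL
  message(sprintf("sample %s: %d duplicate variant key(s) collapsed (kept deeper record)",
                  sample_id, n_dup))
  df
}

#' Construct a SampleVariants object
#'
#' @param sample_id sample identifier.
#' @param calls data.frame with at least `chrom`, `pos`, `ref`, `alt`,
#'   `ref_count`, `alt_count`; optional `effect_class` (default `"unknown"`).
#'   `maf` is (re)derived from the counts.
#' @param timepoint,purity,stage,nodal,cnv_count sample metadata; see
#'   [SampleVariants-class].
#' @return a validated [SampleVariants-class] object.
#' @examples
#' sv <- SampleVariants("S1", data.frame(
#'   chrom = "1", pos = 100, ref = "A", alt = "T",
#'   ref_count = 60, alt_count = 40))
#' mafs(sv)
#' @export
SampleVariants <- function(sample_id, calls,
                           timepoint = "NA", purity = NA_real_,
                           stage = "NA", nodal = "NA",
                           cnv_count = NA_integer_) {
  new("SampleVariants",
      sampleId  = as.character(sample_id),
      calls     = .canonicalCalls(calls),
      timepoint = as.character(timepoint),
      purity    = as.numeric(purity),
      stage     = as.character(stage),
      nodal     = as.character(nodal),
      cnvCount  = as.integer(cnv_count))
}

#' @describeIn SampleVariants sample identifier accessor.
#' @param x a `SampleVariants` object.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname SampleVariants
#' @export
setMethod("sampleId", "SampleVariants", function(x) x@sampleId)

#' @describeIn SampleVariants call table accessor (one row per SNV).
#' @export
setGeneric("variantCalls", function(x) standardGeneric("variantCalls"))

#' @rdname SampleVariants
#' @export
setMethod("variantCalls", "SampleVariants", function(x) x@calls)

#' @describeIn SampleVariants number of variant observations.
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname SampleVariants
#' @export
setMethod("nVariants", "SampleVariants", function(x) nrow(x@calls))

#' @describeIn SampleVariants the (chrom, pos, ref, alt) key table.
#' @export
setGeneric("variantKeys", function(x) standardGeneric("variantKeys"))

#' @rdname SampleVariants
#' @export
setMethod("variantKeys", "SampleVariants", function(x)
  x@calls[, c("chrom", "pos", "ref", "alt"), drop = FALSE])

#' @describeIn SampleVariants mutant-allele frequencies (unfiltered).
#' @export
setGeneric("mafs", function(x) standardGeneric("mafs"))

#' @rdname SampleVariants
#' @export
setMethod("mafs", "SampleVariants", function(x) x@calls$maf)

#' @describeIn SampleVariants sample timepoint accessor.
#' @export
setGeneric("timepoint", function(x) standardGeneric("timepoint"))

#' @rdname SampleVariants
#' @export
setMethod("timepoint", "SampleVariants", function(x) x@timepoint)

#' @describeIn SampleVariants tumor purity accessor.
#' @export
setGeneric("purity", function(x) standardGeneric("purity"))

#' @rdname SampleVariants
#' @export
setMethod("purity", "SampleVariants", function(x) x@purity)

setMethod("show", "SampleVariants", function(object) {
  cat("SampleVariants object\n")
  cat("  sample:   ", object@sampleId, "\n", sep = "")
  cat("  variants: ", nrow(object@calls), " SNV(s)\n", sep = "")
  cat("  timepoint:", object@timepoint,
      " purity:", ifelse(is.na(object@purity), "NA",
                         format(object@purity)), "\n")
  if (nrow(object@calls) > 0L) {
    m <- object@calls$maf
    m <- m[!is.na(m)]
    if (length(m))
      cat(sprintf("  MAF: median %.3f, range [%.3f, %.3f]\n",
                  median(m), min(m), max(m)))
  }
  invisible(NULL)
})
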