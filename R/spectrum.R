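.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
.SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

.revcomp <- function(s) {
  vapply(strsplit(s, "", fixed = TRUE), function(b)
    paste(rev(unname(.COMPLEMENT[b])), collapse = ""), character(1))
}

# collapse one substitution to its pyrimidine-reference representative
.collapseSub <- function(ref, alt) {
  flip <- ref %in% c("A", "G")
  ref2 <- ifelse(flip, unname(.COMPLEMENT[ref]), ref)
  alt2 <- ifelse(flip, unname(.COMPLEMENT[alt]), alt)
  list(ref = ref2, alt = alt2, flipped = flip,
       class = paste0(ref2, ">", alt2))
}

#' The 96 trinucleotide-context substitution labels
#'
#' Labels in the conventional COSMIC ordering: the six pyrimidine-reference
#' substitution classes C>A, C>G, C>T, T>A, T>C, T>G, each expanded over the
#' 16 flanking-base combinations in alphabetical order, giving
#' `A[C>A]A` through `T[T>G]T`.
#'
#' @return character vector of length 96.
#' @export
sbs96Labels <- function() {
  unlist(lapply(.SUB_CLASSES, function(cls) {
    ref <- substr(cls, 1, 1)
    as.vector(t(outer(.BASES, .BASES, function(p5, p3)
      paste0(p5, "[", cls, "]", p3))))
  }))
}

#' Six-class substitution spectrum of a sample
#'
#' Collapses every SNV to its pyrimidine-reference representation (a G>T
#' change is counted as C>A via reverse complement, and so on) and counts
#' the six substitution classes.  Spectrum shifts between matched samples
#' would indicate a mutational process introduced between the timepoints.
#'
#' @param x a [SampleVariants-class] object.
#' @return object of class `itgh_spectrum`: list with `counts6` (named
#'   integer vector over the six classes), `counts96` (`NULL` here; see
#'   [contextSpectrum()]) and `n_total`.
#' @export
substitutionSpectrum <- function(x) {
  stopifnot(is(x, "SampleVariants"))
  calls <- variantCalls(x)
  counts <- setNames(integer(6), .SUB_CLASSES)
  if (nrow(calls) > 0L) {
    cls <- .collapseSub(calls$ref, calls$alt)$class
    t6 <- table(factor(cls, levels = .SUB_CLASSES))
    counts[] <- as.integer(t6)
  }
  structure(list(counts6 = counts, counts96 = NULL,
                 n_total = sum(counts)),
            class = "itgh_spectrum")
}

#' 96-context substitution spectrum
#'
#' Bins every SNV by substitution class and flanking trinucleotide context,
#' pyrimidine-collapsed jointly: a `T[G>T]C` observation reverse-complements
#' to the `G[C>A]A` bin.  Contexts are caller-supplied (the simulator emits
#' them; for real data derive them from a reference genome upstream) because
#' the package performs no genome lookups.
#'
#' @param x a [SampleVariants-class] object.
#' @param contexts data.frame mapping variant keys to contexts: columns
#'   `chrom`, `pos`, `ref`, `alt`, `context` (3 bases, middle base equal to
#'   `ref`).
#' @return object of class `itgh_spectrum` with both `counts6` and
#'   `counts96` (named by [sbs96Labels()]) populated; the 6-class counts are
#'   the marginal of the 96.
#' @export
contextSpectrum <- function(x, contexts) {
  stopifnot(is(x, "SampleVariants"), is.data.frame(contexts))
  need <- c("chrom", "pos", "ref", "alt", "context")
  if (!all(need %in% names(contexts)))
    stop("contexts must have columns: ", paste(need, collapse = ", "))
  calls <- variantCalls(x)
  labels <- sbs96Labels()
  counts96 <- setNames(integer(96), labels)
  if (nrow(calls) > 0L) {
    idx <- match(.keyString(calls), .keyString(contexts))
    if (anyNA(idx))
      stop("missing context for variant(s): ",
           paste(.keyString(calls)[is.na(idx)], collapse = ", "))
    ctx <- toupper(as.character(contexts$context[idx]))
    bad <- nchar(ctx) != 3L | substr(ctx, 2, 2) != calls$ref
    if (any(bad))
      stop("context middle base does not match ref for variant(s): ",
           paste(.keyString(calls)[bad], collapse = ", "))
    col <- .collapseSub(calls$ref, calls$alt)
    ctx2 <- ifelse(col$flipped, .revcomp(ctx), ctx)
    bin <- paste0(substr(ctx2, 1, 1), "[", col$class, "]",
                  substr(ctx2, 3, 3))
    t96 <- table(factor(bin, levels = labels))
    counts96[] <- as.integer(t96)
  }
  counts6 <- vapply(.SUB_CLASSES, function(cls)
    sum(counts96[grepl(cls, names(counts96), fixed = TRUE)]), integer(1))
  structure(list(counts6 = counts6, counts96 = counts96,
                 n_total = sum(counts96)),
            class = "itgh_spectrum")
}

#' @export
print.itgh_spectrum <- function(x, ...) {
  cat("Substitution spectrum (", x$n_total, " SNVs)\n", sep = "")
  for (cls in names(x$counts6))
    cat(sprintf("  %s: %d (%.1f%%)\n", cls, x$counts6[[cls]],
                if (x$n_total > 0) 100 * x$counts6[[cls]] / x$n_total else 0))
  if (!is.null(x$counts96))
    cat("  (96-context counts present)\n")
  invisible(x)
}

#' Refit signature exposures against a supplied signature matrix
#'
#' Non-negative least-squares fit of a normalized 96-context mutation
#' spectrum against a fixed signature matrix (e.g. COSMIC signatures the
#' user supplies): exposures are the mixture weights of the signatures that
#' best reconstruct the observed spectrum.  De novo signature extraction is
#' out of scope; this answers "is a given signature detectable in this
#' sample", with the residual norm as goodness-of-fit.
#'
#' @param counts96 length-96 non-negative count (or proportion) vector,
#'   ordered as [sbs96Labels()]; not all zero.
#' @param signatures 96 x k matrix; each column a signature summing to 1.
#' @return list with `exposures` (length k, non-negative, summing to 1
#'   unless the fit is degenerate at all-zero weights) and `residual` (the
#'   Euclidean residual norm of the normalized fit).
#' @export
signatureExposures <- function(counts96, signatures) {
  signatures <- as.matrix(signatures)
  if (length(counts96) != 96L || nrow(signatures) != 96L)
    stop("counts96 must have length 96 and signatures 96 rows")
  if (any(counts96 < 0)) stop("counts must be non-negative")
  if (sum(counts96) == 0) stop("all-zero spectrum cannot be fitted")
  cs <- colSums(signatures)
  if (any(abs(cs - 1) > 1e-6))
    stop("signature columns must each sum to 1")
  y <- counts96 / sum(counts96)
  fit <- pracma::lsqnonneg(signatures, y)
  w <- fit$x
  total <- sum(w)
  exposures <- if (total > 0) w / total else w
  names(exposures) <- colnames(signatures)
  list(exposures = exposures,
       residual = sqrt(sum((signatures %*% w - y)^2)))
}

#' Read a signature matrix in COSMIC-style TSV layout
#'
#' First column: the 96 context labels (any order; matched against
#' [sbs96Labels()]); remaining columns: one signature each.
#'
#' @param path TSV file.
#' @return 96 x k numeric matrix, rows reordered to the canonical label
#'   order.
#' @export
readSignatureMatrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  labels <- as.character(df[[1]])
  if (!setequal(labels, sbs96Labels()))
    stop("first column must contain the 96 context labels (A[C>A]A ... T[T>G]T)")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- labels
  m[sbs96Labels(), , drop = FALSE]
}
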