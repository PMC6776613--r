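# fixture builders shared across the suite; everything is generated in code

# quick SampleVariants from parallel count vectors
makeSample <- function(sample_id, pos, ref_count, alt_count,
                       ref = "A", alt = "T", chrom = "1",
                       effect = "unknown", ...) {
  n <- length(pos)
  SampleVariants(sample_id, data.frame(
    chrom = rep_len(chrom, n), pos = pos,
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    ref_count = rep_len(ref_count, n), alt_count = rep_len(alt_count, n),
    effect_class = rep_len(effect, n), stringsAsFactors = FALSE), ...)
}

# random SampleVariants for property-style tests
randomSample <- function(sample_id, n, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  depth <- sample(20:200, n, replace = TRUE)
  altc <- rbinom(n, depth, runif(n, 0.05, 0.6))
  SampleVariants(sample_id, data.frame(
    chrom = sample(c("1", "2", "X"), n, replace = TRUE),
    pos = sample.int(1e6, n), ref = ref, alt = alt,
    ref_count = depth - altc, alt_count = altc,
    effect_class = sample(c("synonymous", "nonsynonymous", "splice",
                            "noncoding"), n, replace = TRUE),
    stringsAsFactors = FALSE))
}

# minimal VCF 4.2 writer: records as list(chrom, pos, ref, alt, ad) where
# ad is the per-sample AD string; format_dp adds a DP field
writeTinyVcf <- function(path, records, sample_id = "S1") {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_id))
  body <- vapply(records, function(r) {
    fmt <- if (is.null(r$ad)) "GT" else "GT:AD"
    smp <- if (is.null(r$ad)) "0/1" else paste0("0/1:", r$ad)
    paste(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", ".", fmt, smp,
          sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# minimal TCGA-style MAF writer from a data.frame of the required columns
writeTinyMaf <- function(path, df) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# disjoint-support toy signature matrix (96 x 2), columns sum to 1
toySignatures <- function() {
  labels <- sbs96Labels()
  s1 <- rep(0, 96); s2 <- rep(0, 96)
  s1[1:48] <- 1 / 48     # all C>A, C>G, C>T contexts
  s2[49:96] <- 1 / 48    # all T>A, T>C, T>G contexts
  matrix(c(s1, s2), ncol = 2,
         dimnames = list(labels, c("sig1", "sig2")))
}
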