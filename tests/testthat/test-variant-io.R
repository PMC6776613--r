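test_that("SampleVariants validity enforces the variant-observation contract", {
  expect_s4_class(makeSample("S1", 1:3, 50, 50), "SampleVariants")
  # duplicate keys rejected at the class level
  expect_error(SampleVariants("S1", data.frame(
    chrom = "1", pos = c(5, 5), ref = "A", alt = "T",
    ref_count = c(10, 20), alt_count = c(5, 5))), "duplicate")
  expect_error(makeSample("S1", 0, 10, 10), "1-based")
  expect_error(SampleVariants("S1", data.frame(
    chrom = "1", pos = 1, ref = "A", alt = "A",
    ref_count = 1, alt_count = 1)), "differ")
  expect_error(SampleVariants("S1", data.frame(
    chrom = "1", pos = 1, ref = "AT", alt = "G",
    ref_count = 1, alt_count = 1)), "single bases")
  # maf derivation, including zero-depth NA
  sv <- makeSample("S1", 1:2, c(60, 0), c(40, 0))
  expect_equal(mafs(sv), c(0.4, NA))
})

test_that("VCF reader extracts biallelic SNVs, splits multi-allelics, drops non-SNVs", {
  vcf <- writeTinyVcf(withr::local_tempfile(fileext = ".vcf"), list(
    list(chrom = "chr1", pos = 100, ref = "A", alt = "T", ad = "60,40"),
    list(chrom = "chr1", pos = 200, ref = "A", alt = "AT", ad = "50,50"),
    list(chrom = "chr2", pos = 300, ref = "A", alt = "T,G", ad = "50,30,20")))
  sv <- readVariantVcf(vcf, "S1")
  calls <- variantCalls(sv)
  expect_equal(nrow(calls), 3L)            # insertion dropped, triallelic split
  expect_equal(calls$maf[calls$pos == 100], 0.40)
  m <- sort(calls$maf[calls$pos == 300])
  expect_equal(m, c(0.20, 0.30))           # AD triplet hand-split
  expect_equal(sum(calls$pos == 200), 0L)
  # chr prefix normalization is opt-in
  expect_true(all(grepl("^chr", calls$chrom)))
  sv2 <- readVariantVcf(vcf, "S1", strip_chr_prefix = TRUE)
  expect_true(all(variantCalls(sv2)$chrom %in% c("1", "2")))
})

test_that("VCF reader errors on unknown sample and warns on unusable records", {
  vcf <- writeTinyVcf(withr::local_tempfile(fileext = ".vcf"), list(
    list(chrom = "1", pos = 100, ref = "A", alt = "T", ad = "60,40"),
    list(chrom = "1", pos = 150, ref = "C", alt = "G")))  # no AD
  expect_error(readVariantVcf(vcf, "NOSUCH"), "NOSUCH")
  expect_warning(sv <- readVariantVcf(vcf, "S1"), "skipped")
  expect_equal(nVariants(sv), 1L)
})

test_that("MAF table reader groups by barcode and maps effect classes", {
  maf <- writeTinyMaf(withr::local_tempfile(fileext = ".maf"), data.frame(
    Chromosome = c("1", "1", "2", "2"),
    Start_Position = c(100, 200, 300, 400),
    Reference_Allele = c("A", "C", "G", "TT"),
    Tumor_Seq_Allele2 = c("T", "T", "A", "A"),
    Tumor_Sample_Barcode = c("TCGA-01", "TCGA-01", "TCGA-02", "TCGA-02"),
    t_ref_count = c(90, 50, 70, 10),
    t_alt_count = c(10, 50, 30, 10),
    Variant_Classification = c("Silent", "Missense_Mutation",
                               "Splice_Site", "Frame_Shift_Del")))
  expect_message(tabs <- readMafCohort(maf), "dropped")   # the TT row
  expect_named(tabs, c("TCGA-01", "TCGA-02"))
  expect_equal(nVariants(tabs[["TCGA-01"]]), 2L)
  expect_equal(nVariants(tabs[["TCGA-02"]]), 1L)
  c1 <- variantCalls(tabs[["TCGA-01"]])
  expect_equal(c1$effect_class[c1$pos == 100], "synonymous")
  expect_equal(c1$effect_class[c1$pos == 200], "nonsynonymous")
  expect_equal(c1$maf[c1$pos == 100], 0.10)
  expect_equal(variantCalls(tabs[["TCGA-02"]])$effect_class, "splice")
})

test_that("MAF reader names the missing column in format errors", {
  maf <- writeTinyMaf(withr::local_tempfile(fileext = ".maf"), data.frame(
    Chromosome = "1", Start_Position = 1, Reference_Allele = "A",
    Tumor_Seq_Allele2 = "T", Tumor_Sample_Barcode = "B"))
  expect_error(readMafCohort(maf), "t_ref_count")
})

test_that("TSV dialect round-trips exactly and is idempotent on re-write", {
  sv <- randomSample("S7", 40, seed = 11)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeVariantTsv(sv, f1)
  back <- readVariantTsv(f1)
  expect_equal(variantCalls(back), variantCalls(sv))
  expect_equal(sampleId(back), "S7")
  writeVariantTsv(back, f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical
  # counts 7/3 reads back with maf 0.3
  one <- makeSample("X", 1, 7, 3)
  writeVariantTsv(one, f1)
  expect_equal(mafs(readVariantTsv(f1)), 0.3)
})

test_that("TSV reader handles empty tables, comments, and malformed rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeVariantTsv(makeSample("E", integer(0), integer(0), integer(0)), f,
                  provenance = "test run")
  sv <- readVariantTsv(f)
  expect_equal(nVariants(sv), 0L)
  lines <- readLines(f)
  expect_true(startsWith(lines[1], "#"))
  writeLines(c("sample_id\tchrom\tpos\tref\talt\tref_count\talt_count\teffect_class",
               "S\t1\tnot_a_number\tA\tT\t5\t5\tunknown"), f)
  expect_error(readVariantTsv(f), "line 2")
  writeLines(c("wrong\theader"), f)
  expect_error(readVariantTsv(f), "header")
})

test_that("VCF and TSV readers agree on equivalent content", {
  vcf <- writeTinyVcf(withr::local_tempfile(fileext = ".vcf"), list(
    list(chrom = "1", pos = 100, ref = "A", alt = "T", ad = "60,40"),
    list(chrom = "2", pos = 50, ref = "C", alt = "G", ad = "90,10")))
  from_vcf <- readVariantVcf(vcf, "S1")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeVariantTsv(from_vcf, tsv)
  from_tsv <- readVariantTsv(tsv)
  expect_equal(variantCalls(from_tsv), variantCalls(from_vcf))
})

test_that("partition obeys set algebra and conservation on random tables", {
  a <- makeSample("a", 1:2, 50, 50)
  b <- makeSample("b", 2:3, 50, 50)
  p <- partitionVariants(a, b)
  expect_equal(p$shared$pos, 2L)
  expect_equal(p$a_only$pos, 1L)
  expect_equal(p$b_only$pos, 3L)
  expect_equal(sharedFraction(p, "a"), 0.5)
  # identical tables: no private variants
  p_id <- partitionVariants(a, a)
  expect_equal(nrow(p_id$a_only), 0L)
  expect_equal(nrow(p_id$b_only), 0L)
  # 2 shared of 3 presented as 66.7%
  a3 <- makeSample("a", 1:3, 50, 50)
  b3 <- makeSample("b", 2:4, 50, 50)
  expect_equal(round(100 * sharedFraction(partitionVariants(a3, b3), "a"), 1),
               66.7)
  # conservation property over random pairs
  for (s in 1:10) {
    x <- randomSample("x", 30, seed = s)
    y <- randomSample("y", 30, seed = s + 100)
    p <- partitionVariants(x, y)
    expect_equal(nrow(p$shared) + nrow(p$a_only) + nrow(p$b_only), p$n_union)
  }
})

test_that("duplicate keys at ingest keep the deeper record with a message", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tchrom\tpos\tref\talt\tref_count\talt_count\teffect_class",
               "S\t1\t10\tA\tT\t5\t5\tunknown",
               "S\t1\t10\tA\tT\t80\t20\tunknown"), f)
  expect_message(sv <- readVariantTsv(f), "collapsed")
  expect_equal(variantCalls(sv)$ref_count, 80L)
})
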