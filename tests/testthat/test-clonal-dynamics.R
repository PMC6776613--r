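# independent oracle: literal enumeration of all outcomes no likelier than
# the observed one (same floating-point tie tolerance as the implementation)
oracleBinomP <- function(alt, depth, p0) {
  p_obs <- choose(depth, alt) * p0^alt * (1 - p0)^(depth - alt)
  total <- 0
  for (k in 0:depth) {
    pk <- choose(depth, k) * p0^k * (1 - p0)^(depth - k)
    if (pk <= p_obs * (1 + 1e-7)) total <- total + pk
  }
  min(1, total)
}

test_that("binomial shift test reproduces closed forms and rejects bad input", {
  expect_equal(binomialShiftTest(5, 10, 0.5), 1.0)
  expect_equal(binomialShiftTest(0, 20, 0.5), 2 * 0.5^20)
  expect_equal(binomialShiftTest(10, 10, 0.2), 0.2^10)
  expect_error(binomialShiftTest(1, 10, 0), "p0")
  expect_error(binomialShiftTest(1, 10, 1), "p0")
  expect_error(binomialShiftTest(11, 10, 0.5), "alt")
})

test_that("minlike p equals exhaustive enumeration for all depth <= 30", {
  for (p0 in c(0.1, 0.25, 0.5)) {
    for (depth in c(1:10, 15, 20, 30)) {
      alts <- 0:depth
      got <- binomialShiftTest(alts, depth, p0)
      want <- vapply(alts, oracleBinomP, numeric(1), depth = depth, p0 = p0)
      expect_equal(got, want)
    }
  }
})

test_that("minlike p agrees with the standard exact binomial test", {
  set.seed(9)
  for (i in 1:200) {
    depth <- sample(1:120, 1)
    alt <- sample(0:depth, 1)
    p0 <- runif(1, 0.05, 0.95)
    expect_equal(binomialShiftTest(alt, depth, p0),
                 binom.test(alt, depth, p0)$p.value, tolerance = 1e-12)
  }
})

test_that("central two-sided variant is a valid doubled-tail p-value", {
  set.seed(10)
  for (i in 1:100) {
    depth <- sample(5:80, 1)
    alt <- sample(0:depth, 1)
    p0 <- runif(1, 0.1, 0.9)
    p <- binomialShiftTest(alt, depth, p0, method = "central")
    expect_gte(p, 0); expect_lte(p, 1)
    lo <- pbinom(alt, depth, p0)
    hi <- pbinom(alt - 1, depth, p0, lower.tail = FALSE)
    expect_equal(p, min(1, 2 * min(lo, hi)))
  }
})

test_that("p-value adjustment matches hand-worked examples and orderings", {
  expect_equal(adjustPvalues(0.03, "bonferroni"), 0.03)
  expect_equal(adjustPvalues(0.03, "bh"), 0.03)
  expect_equal(adjustPvalues(c(0.01, 0.04), "bonferroni"), c(0.02, 0.08))
  expect_equal(adjustPvalues(c(0.01, 0.02, 0.03), "bh"), c(0.03, 0.03, 0.03))
  # dominance: bonferroni >= bh >= raw, both capped at 1
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))
    bon <- adjustPvalues(p, "bonferroni")
    bh <- adjustPvalues(p, "bh")
    expect_true(all(bon >= bh - 1e-12))
    expect_true(all(bh >= p - 1e-12))
    expect_true(all(bon <= 1) && all(bh <= 1))
  }
})

test_that("comparePaired classifies enrichment and respects its filters", {
  # strong drop in B: enriched in A even after correction
  a <- makeSample("PRE", 1:3, c(50, 50, 50), c(50, 50, 50),
                  effect = "nonsynonymous")
  b <- makeSample("POST", 1:3, c(90, 50, 50), c(10, 50, 50),
                  effect = "nonsynonymous")
  cmp <- comparePaired(a, b, alpha = 0.05, method = "bonferroni")
  expect_equal(nrow(cmp), 3L)
  expect_equal(cmp$enriched_in[cmp$pos == 1], "A")
  expect_equal(cmp$direction[cmp$pos == 1], "down_in_b")
  expect_equal(cmp$enriched_in[cmp$pos == 2], "none")
  expect_true(all(cmp$p_adj >= cmp$p_raw))
  # coding/splice restriction drops noncoding variants
  a2 <- makeSample("PRE", 1:2, 50, 50, effect = c("noncoding", "synonymous"))
  b2 <- makeSample("POST", 1:2, 50, 50, effect = c("noncoding", "synonymous"))
  expect_equal(nrow(comparePaired(a2, b2)), 1L)
  expect_equal(nrow(comparePaired(a2, b2, restrict_coding_splice = FALSE)), 2L)
  # reference MAF 0 or 1 is untestable, excluded with a message
  a3 <- makeSample("PRE", 1:2, c(100, 50), c(0, 50), effect = "synonymous")
  b3 <- makeSample("POST", 1:2, c(50, 50), c(50, 50), effect = "synonymous")
  expect_message(cmp3 <- comparePaired(a3, b3), "excluded")
  expect_equal(nrow(cmp3), 1L)
  expect_equal(attr(cmp3, "n_untestable"), 1L)
  # zero shared variants: empty result, not an error
  a4 <- makeSample("PRE", 1, 50, 50, effect = "synonymous")
  b4 <- makeSample("POST", 2, 50, 50, effect = "synonymous")
  expect_equal(nrow(comparePaired(a4, b4)), 0L)
})

test_that("swapping the samples mirrors enrichment sides on symmetric input", {
  a <- makeSample("PRE", 1:4, c(50, 95, 60, 55), c(50, 5, 40, 45),
                  effect = "nonsynonymous")
  b <- makeSample("POST", 1:4, c(95, 50, 60, 55), c(5, 50, 40, 45),
                  effect = "nonsynonymous")
  ab <- comparePaired(a, b)
  ba <- comparePaired(b, a)
  map <- c(A = "B", B = "A", none = "none")
  expect_equal(unname(map[ab$enriched_in[order(ab$pos)]]),
               ba$enriched_in[order(ba$pos)])
})

test_that("nsRatio reproduces the published ratios and handles zero synonymous", {
  cmp <- data.frame(
    effect_class = c(rep("nonsynonymous", 136), rep("synonymous", 46),
                     rep("nonsynonymous", 8), rep("synonymous", 5)),
    enriched_in = c(rep("B", 182), rep("A", 13)),
    stringsAsFactors = FALSE)
  expect_equal(round(nsRatio(cmp, "B"), 2), 2.96)
  expect_equal(nsRatio(cmp, "A"), 1.6)
  balanced <- data.frame(effect_class = rep(c("nonsynonymous", "synonymous"),
                                            each = 4),
                         enriched_in = "B", stringsAsFactors = FALSE)
  expect_equal(nsRatio(balanced, "B"), 1.0)
  no_syn <- data.frame(effect_class = "nonsynonymous", enriched_in = "B",
                       stringsAsFactors = FALSE)
  expect_true(is.na(nsRatio(no_syn, "B")))
})

test_that("fisher2x2 matches hypergeometric enumeration and handles edge tables", {
  expect_equal(fisher2x2(matrix(c(5, 0, 0, 5), 2))$p, 2 / 252)
  expect_equal(fisher2x2(matrix(c(3, 3, 3, 3), 2))$p, 1.0)
  # published N/S contrast table: one-sided reproduces the printed 0.23
  tab <- matrix(c(136, 8, 46, 5), nrow = 2)
  expect_equal(round(fisher2x2(tab, alternative = "greater")$p, 2), 0.23)
  expect_equal(fisher2x2(tab)$p, fisher.test(tab)$p.value)
  expect_error(fisher2x2(matrix(0, 2, 2)), "all-zero")
  expect_error(fisher2x2(matrix(1:6, 2)), "2x2")
})

test_that("mafConcordance recovers exact and degenerate correlations", {
  a <- makeSample("a", 1:4, c(90, 70, 50, 30), c(10, 30, 50, 70))
  expect_equal(mafConcordance(a, a), list(r = 1, r2 = 1, n = 4))
  b <- makeSample("b", 1:4, c(10, 30, 50, 70), c(90, 70, 50, 30))
  anti <- mafConcordance(a, b)
  expect_equal(anti$r, -1)
  expect_equal(anti$r2, 1)
  # hand-computed 5-point Pearson
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  y <- c(0.12, 0.18, 0.33, 0.41, 0.46)
  a5 <- makeSample("a", 1:5, round(100 * (1 - x)), round(100 * x))
  b5 <- makeSample("b", 1:5, round(100 * (1 - y)), round(100 * y))
  got <- mafConcordance(a5, b5)
  xm <- round(100 * x) / 100; ym <- round(100 * y) / 100
  hand <- sum((xm - mean(xm)) * (ym - mean(ym))) /
    sqrt(sum((xm - mean(xm))^2) * sum((ym - mean(ym))^2))
  expect_equal(got$r, hand, tolerance = 1e-12)
  # fewer than 3 shared: unavailable
  few <- mafConcordance(makeSample("a", 1:2, 50, 50),
                        makeSample("b", 1:2, 50, 50))
  expect_true(is.na(few$r))
  expect_equal(few$n, 2L)
})

test_that("summarizeEnrichment aggregates counts, fractions and the N/S contrast", {
  cmp <- data.frame(
    effect_class = c(rep("nonsynonymous", 136), rep("synonymous", 46),
                     rep("nonsynonymous", 8), rep("synonymous", 5),
                     rep("nonsynonymous", 191)),
    enriched_in = c(rep("B", 182), rep("A", 13), rep("none", 191)),
    stringsAsFactors = FALSE)
  s <- summarizeEnrichment(cmp)
  expect_equal(s$n_shared_tested, 386L)
  expect_equal(s$n_enriched, 195L)
  expect_equal(s$n_enriched, s$n_enriched_a + s$n_enriched_b)
  expect_equal(round(nsRatio(cmp, "B"), 2), s$ns_ratio_b, tolerance = 0.005)
  expect_equal(s$ns_ratio_a, 1.6)
  expect_false(is.na(s$fisher_p))
  # zero enriched: counts 0, ratios unavailable
  none <- data.frame(effect_class = "synonymous", enriched_in = "none",
                     stringsAsFactors = FALSE)
  s0 <- summarizeEnrichment(none)
  expect_equal(s0$n_enriched, 0L)
  expect_true(is.na(s0$ns_ratio_a) && is.na(s0$ns_ratio_b))
})
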