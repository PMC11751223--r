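test_that("Pearson r and p match the closed-form and stats::cor.test", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- pearsonWithP(x, y)
    rManual <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(got$r, rManual, tolerance = 1e-12)
    ct <- cor.test(x, y)
    expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(got$p, ct$p.value, tolerance = 1e-12)
    # affine invariance / sign flip under negative scaling
    expect_equal(pearsonWithP(2 * x + 3, y)$r, got$r, tolerance = 1e-12)
    expect_equal(pearsonWithP(-x, y)$r, -got$r, tolerance = 1e-12)
  }
})

test_that("Pearson edge cases: perfect linearity, small fixed example, constants", {
  perf <- pearsonWithP(1:5, 2 * (1:5) + 1)
  expect_equal(perf$r, 1)
  expect_lt(perf$p, 1e-10)
  ex <- pearsonWithP(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(ex$r, 0.8, tolerance = 1e-12)
  tstat <- 0.8 * sqrt(2 / (1 - 0.64))
  expect_equal(ex$p, 2 * pt(-tstat, 2), tolerance = 1e-12)
  expect_error(pearsonWithP(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearsonWithP(1:2, 2:3), "at least 3")
})

test_that("the strong-hit rule uses |r| with raw p-values", {
  expect_true(flagStrong(0.76, 0.01))
  expect_true(flagStrong(-0.68, 0.01))
  expect_false(flagStrong(0.60, 0.01))
  expect_false(flagStrong(0.66, 0.2))
  expect_false(flagStrong(0.65, 0.01))   # strict inequality on both
  expect_false(flagStrong(0.7, 0.05))
  # signed mode demands positive correlation
  expect_false(flagStrong(-0.68, 0.01, signed = TRUE))
  expect_equal(flagStrong(c(0.9, -0.9, 0.1), c(0.01, 0.01, 0.01)),
               c(TRUE, TRUE, FALSE))
})

test_that("the screen recovers a driving element and excludes unusable ones", {
  set.seed(123)
  co <- simulateScreenCohort(nMites = 30, rTrue = 0.9)
  hits <- screenMitePhenotype(co$levels, co$phenotypes, co$links,
                              "plant_height")
  expect_equal(hits$mite_id[1], co$target)
  expect_true(hits$strong[1])
  expect_equal(hits$n[1], 18)
  # sorted by |r| descending
  expect_true(all(diff(abs(hits$r)) <= 1e-12))
  # elements undefined in over half the samples are excluded
  lev <- co$levels
  lev[2, 1:10] <- NA
  expect_message(
    hits2 <- screenMitePhenotype(lev, co$phenotypes, co$links,
                                 "plant_height"),
    "excluded")
  expect_false(co$links$mite_id[2] %in% hits2$mite_id)
  expect_error(screenMitePhenotype(co$levels, co$phenotypes, co$links,
                                   "no_such_trait"), "absent")
  # BH adjustment is monotone in p when requested
  hits3 <- screenMitePhenotype(co$levels, co$phenotypes, co$links,
                               "plant_height", adjust = TRUE)
  expect_true(all(hits3$q >= hits3$p - 1e-15))
})

test_that("ddCt fold changes follow 2^-ddCt with replicate averaging", {
  expect_equal(ddctFoldChange(20, 18, 22, 18)$ddct, -2)
  expect_equal(ddctFoldChange(20, 18, 22, 18)$fold, 4)
  expect_equal(ddctFoldChange(20, 20, 20, 20)$fold, 1)
  expect_equal(ddctFoldChange(21, 20, 20, 20)$fold, 0.5)
  # replicates are averaged before differencing
  expect_equal(ddctFoldChange(c(19, 21), c(18, 18), 22, 18)$ddct, -2)
  expect_error(ddctFoldChange(NA, 1, 1, 1), "finite")
})

test_that("group difference tests match the textbook t formulas", {
  set.seed(9)
  a <- rnorm(8); b <- rnorm(6, 1)
  got <- groupDifferenceTest(a, b)
  sp2 <- (7 * var(a) + 5 * var(b)) / 12
  tManual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 8 + 1 / 6))
  expect_equal(got$statistic, tManual, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(tManual), 12), tolerance = 1e-12)
  # identical groups give a zero statistic
  expect_equal(groupDifferenceTest(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  # single-sample mode against a fixed reference
  one <- groupDifferenceTest(c(1, 2, 3), reference = 2)
  expect_equal(one$statistic, 0)
  expect_equal(one$method, "single-sample")
  expect_equal(groupDifferenceTest(c(1, 2, 3), reference = 0)$statistic,
               mean(1:3) / (sd(1:3) / sqrt(3)), tolerance = 1e-12)
  expect_error(groupDifferenceTest(c(1, 1, 1), c(2, 2, 2)), "variance")
})

test_that("chromatin fractions classify insertion points and report gaps", {
  map <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 5001), c(5000, 8000)),
    state = c("euchromatin", "heterochromatin"))
  mkLoci <- function(pos) GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(pos, pos + 2), locus_id = paste0("L", pos))
  allEu <- chromatinFraction(mkLoci(c(100, 2000, 4900)), map)
  expect_equal(allEu$fraction, 1)
  mix <- chromatinFraction(mkLoci(c(seq(100, 4500, length.out = 9), 6000)),
                           map)
  expect_equal(mix$fraction, 0.9)
  expect_equal(mix$n_heterochromatin, 1)
  # a locus beyond the annotated intervals counts as gap, not as either state
  expect_message(gap <- chromatinFraction(mkLoci(c(100, 9000)), map),
                 "gap")
  expect_equal(gap$fraction, 1)
  expect_equal(gap$n_gap, 1)
  expect_error(chromatinFraction(mkLoci(100)[0], map), "no loci")
})

test_that("bin counts conserve totals and split exactly at bin boundaries", {
  sizes <- c(chr1 = 3.5e6)
  # 0-based 999,999 and 1,000,000 are 1-based 1e6 and 1e6 + 1
  loci <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(1e6, 1e6 + 1), width = 2))
  bc <- binCounts(loci, sizes)
  expect_equal(bc$count, c(1, 1, 0, 0))
  expect_equal(bc$bin_start, c(0, 1, 2, 3) * 1e6)
  expect_equal(bc$bin_end[4], 3.5e6)
  # empty input emits all-zero bins; totals are conserved
  expect_equal(sum(binCounts(loci[0], sizes)$count), 0)
  expect_equal(nrow(binCounts(loci[0], sizes)), 4)
  set.seed(31)
  many <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(sample(3.4e6, 57), width = 3))
  expect_equal(sum(binCounts(many, sizes)$count), 57)
  beyond <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4e6, 4e6))
  expect_error(binCounts(beyond, sizes), "beyond")
})
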