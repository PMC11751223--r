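cxLines <- function(df) {
  apply(df, 1, paste, collapse = "\t")
}

test_that("CX reports parse with 1-based positions and normalised contexts", {
  f <- tempfile()
  writeLines(c("chr1\t101\t+\t4\t1\tCG\tCGA",
               "chr1\t205\t-\t0\t7\tCHH\tCAT"), f)
  calls <- readCXReport(f)
  expect_equal(length(calls), 2)
  expect_equal(GenomicRanges::start(calls), c(101, 205))
  expect_equal(calls$nMeth, c(4, 0))
  expect_equal(calls$nUnmeth, c(1, 7))
  expect_equal(calls$context, c("CpG", "CHH"))
  # empty report gives an empty stream
  f2 <- tempfile(); file.create(f2)
  expect_equal(length(readCXReport(f2)), 0)
  # corrupt counts are rejected with a line number
  f3 <- tempfile()
  writeLines(c("chr1\t101\t+\t4\t1\tCG\tCGA",
               "chr1\t102\t+\tx\t1\tCG\tCGA"), f3)
  expect_error(readCXReport(f3), "line 2")
})

miteFixture <- function(counts, start = 1001) {
  # one element covering length(counts) consecutive cytosines
  n <- nrow(counts)
  mites <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start, start + n - 1L), mite_id = "m1")
  calls <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start + seq_len(n) - 1L, width = 1),
    strand = "+", nMeth = counts$m, nUnmeth = counts$u, context = "CpG")
  list(mites = mites, calls = calls)
}

test_that("weighted and positional estimators reproduce hand-computed levels", {
  fx <- miteFixture(data.frame(m = c(4, 0, 3), u = c(1, 5, 2)))
  w <- miteMethylationLevels(fx$mites, fx$calls, mode = "weighted")
  expect_equal(w$level, 7 / 15)
  expect_equal(w$covered_c, 3)
  p <- miteMethylationLevels(fx$mites, fx$calls, mode = "positional")
  # methylated fractions 0.8, 0.0, 0.6; two of three positions >= 0.5
  expect_equal(p$level, 2 / 3)
  # fully unmethylated element is 0, not undefined
  fx0 <- miteFixture(data.frame(m = c(0, 0), u = c(3, 4)))
  expect_equal(miteMethylationLevels(fx0$mites, fx0$calls)$level, 0)
  # uncovered element is undefined, not 0
  empty <- miteFixture(data.frame(m = 5, u = 0), start = 5000)
  res <- miteMethylationLevels(fx$mites, empty$calls)
  expect_true(is.na(res$level))
  expect_equal(res$covered_c, 0)
})

test_that("weighted level equals the depth-weighted mean of per-position fractions", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:40, 1)
    depth <- rpois(n, 15) + 1
    m <- rbinom(n, depth, runif(1, 0.1, 0.9))
    fx <- miteFixture(data.frame(m = m, u = depth - m))
    got <- miteMethylationLevels(fx$mites, fx$calls)$level
    expect_equal(got, sum(depth * (m / depth)) / sum(depth))
  }
})

test_that("differential methylation is the difference to the control mean", {
  d <- differentialMethylation(0.8, c(0.5, 0.6, 0.7))
  expect_equal(d$delta, 0.2)
  expect_equal(d$n_controls, 3)
  expect_equal(differentialMethylation(0.6, c(0.5, 0.6, 0.7))$delta, 0)
  expect_equal(differentialMethylation(0, c(1, 1, 1))$delta, -1)
  # vectorised over elements with a control matrix
  dm <- differentialMethylation(c(0.2, 0.9),
                                matrix(c(0.1, 0.5, 0.3, 0.7), 2))
  expect_equal(dm$delta, c(0.2, 0.9) - c(0.2, 0.6))
  expect_error(differentialMethylation(0.5, numeric(0)), "control")
})

test_that("hyper/hypo/unchanged proportions partition the elements exactly", {
  p <- hyperHypoProportions(c(0.1, -0.2, 0, 0.3))
  expect_equal(unname(p), c(0.5, 0.25, 0.25))
  expect_equal(unname(hyperHypoProportions(c(0.2, 0.1))), c(1, 0, 0))
  expect_error(hyperHypoProportions(numeric(0)), "undefined")
  # exact unit sum on random delta sets
  for (seed in 1:20) {
    set.seed(seed)
    d <- round(runif(sample(3:200, 1), -1, 1), 3)
    p <- hyperHypoProportions(d, epsilon = runif(1, 0, 0.3))
    expect_identical(sum(p), 1)
  }
})

test_that("stability SD matches closed forms and is shift/permutation invariant", {
  expect_equal(stabilitySD(c(0.5, 0.5, 0.5)), 0)
  expect_equal(stabilitySD(c(0.2, 0.4, 0.6)), 0.2)
  expect_equal(stabilitySD(c(0, 1)), sqrt(0.5))
  expect_error(stabilitySD(0.4), "at least 2")
  set.seed(3)
  x <- runif(6)
  expect_equal(stabilitySD(x), stabilitySD(sample(x)))
  expect_equal(stabilitySD(x), stabilitySD(x + 0.123))
})

test_that("stability report aggregates proportions per line and generation", {
  set.seed(8)
  deltas <- matrix(runif(60, -0.5, 0.5), 10,
                   dimnames = list(NULL, paste0("s", 1:6)))
  info <- data.frame(sample_id = paste0("s", 1:6),
                     line = rep(c("L1", "L2"), each = 3),
                     generation = "F3")
  rep <- stabilityReport(deltas, info)
  expect_equal(nrow(rep$perSample), 6)
  expect_equal(rowSums(rep$perSample[, c("p_hyper", "p_hypo",
                                         "p_unchanged")]),
               rep(1, 6), ignore_attr = TRUE)
  expect_equal(nrow(rep$perGeneration), 2)
  l1 <- rep$perSample$p_hyper[rep$perSample$line == "L1"]
  expect_equal(rep$perGeneration$sd_hyper[rep$perGeneration$line == "L1"],
               sd(l1))
})

test_that("methylation matrix assembles a SummarizedExperiment across samples", {
  set.seed(21)
  n <- 5
  mites <- MiteSet(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(seq(1000, by = 500, length.out = n),
                             width = 100),
    mite_id = paste0("m", 1:n)))
  files <- sapply(c("sampleA", "sampleB"), function(s) {
    f <- tempfile()
    pos <- unlist(lapply(GenomicRanges::start(miteRanges(mites)),
                         function(st) st + 0:9))
    writeLines(sprintf("chr1\t%d\t+\t%d\t%d\tCG\tCGG", pos,
                       rbinom(length(pos), 10, 0.5),
                       rbinom(length(pos), 10, 0.5)), f)
    f
  })
  se <- methylationMatrix(mites, files)
  expect_s4_class(se, "SummarizedExperiment")
  expect_equal(dim(se), c(n, 2))
  lev <- SummarizedExperiment::assay(se, "level")
  expect_true(all(lev >= 0 & lev <= 1))
  expect_equal(unname(SummarizedExperiment::assay(se, "covered")[1, 1]), 10)
})
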