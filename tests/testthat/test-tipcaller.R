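test_that("a target site duplication is read out between paired clusters", {
  set.seed(10)
  ref <- Biostrings::DNAStringSet(setNames(randomSeq(5000), "chr1"))
  left <- data.frame(chrom = "chr1", position = 1001L, side = "left_clip")
  right <- data.frame(chrom = "chr1", position = 1003L,
                      side = "right_clip")
  tsd <- detectTsd(left, right, ref)
  expect_equal(tsd, as.character(Biostrings::subseq(ref[[1]], 1001, 1003)))
  expect_equal(nchar(tsd), 3)
  # offsets outside the duplication range yield nothing
  expect_null(detectTsd(left, transform(right, position = 1001L), ref))
  expect_null(detectTsd(left, transform(right, position = 1016L), ref))
  expect_error(detectTsd(left, transform(right, chrom = "chr2"), ref),
               "different chromosomes")
  expect_error(detectTsd(right, left, ref), "expects")
})

test_that("clipped sequences vote for the correct element terminus and orientation", {
  set.seed(12)
  lib <- Biostrings::DNAStringSet(c(M1 = makeElement(200, 20),
                                    M2 = makeElement(150, 20)))
  e1 <- as.character(lib[["M1"]])
  expect_equal(
    matchMiteLibrary(substr(e1, 1, 40), lib)[c("mite_id", "terminus",
                                               "orientation")],
    list(mite_id = "M1", terminus = "5prime", orientation = "forward"))
  expect_equal(
    matchMiteLibrary(substring(e1, 161, 200), lib)$terminus, "3prime")
  # reverse complement of the element's tail is the reversed insertion's head
  rcTail <- revComp(substring(e1, 161, 200))
  m <- matchMiteLibrary(rcTail, lib)
  expect_equal(m$mite_id, "M1")
  expect_equal(m$terminus, "5prime")
  expect_equal(m$orientation, "reverse")
  # unrelated sequence matches nothing; empty library errors
  expect_null(matchMiteLibrary(randomSeq(40), lib))
  expect_error(matchMiteLibrary("ACGT", Biostrings::DNAStringSet()),
               "library")
  # one mismatch per 10 bp is tolerated, more is not
  mut <- e1
  substr(mut, 5, 5) <- if (substr(mut, 5, 5) == "A") "C" else "A"
  expect_equal(matchMiteLibrary(substr(mut, 1, 20), lib)$mite_id, "M1")
  substr(mut, 6, 6) <- if (substr(mut, 6, 6) == "A") "C" else "A"
  substr(mut, 7, 7) <- if (substr(mut, 7, 7) == "A") "C" else "A"
  expect_null(matchMiteLibrary(substr(mut, 1, 20), lib))
})

test_that("an implanted insertion is recovered with exact breakpoints and TSD", {
  fx <- tipFixture(seed = 21, m5 = c(55, 65, 75, 85), m3 = c(55, 65, 75),
                   nBg = 3)
  calls <- callTips(fx$sam, fx$refSet, fx$lib)
  expect_equal(length(calls), 1)
  expect_equal(GenomicRanges::start(calls), fx$site)
  expect_equal(GenomicRanges::end(calls), fx$site + fx$tsdLen - 1)
  expect_equal(calls$tsd_seq, fx$tsd)
  expect_equal(calls$mite_id, "M1")
  expect_equal(calls$orientation, "forward")
  expect_equal(calls$support_left, 3)
  expect_equal(calls$support_right, 4)
})

test_that("reverse-complementing the insertion flips orientation but not the locus", {
  fwd <- tipFixture(seed = 33, m5 = c(50, 60, 70), m3 = c(50, 60, 70))
  rev <- tipFixture(seed = 33, m5 = c(50, 60, 70), m3 = c(50, 60, 70),
                    orientation = "reverse")
  cf <- callTips(fwd$sam, fwd$refSet, fwd$lib)
  cr <- callTips(rev$sam, rev$refSet, rev$lib)
  expect_equal(cf$orientation, "forward")
  expect_equal(cr$orientation, "reverse")
  expect_equal(GenomicRanges::start(cf), GenomicRanges::start(cr))
  expect_equal(cf$tsd_seq, cr$tsd_seq)
})

test_that("the depth rule rejects 4 overlapping reads and admits 5", {
  # 2 + 2 junction reads = 4 reads over the TSD interval
  fx4 <- tipFixture(seed = 40, m5 = c(60, 70), m3 = c(60, 70))
  expect_equal(length(callTips(fx4$sam, fx4$refSet, fx4$lib,
                               minDepth = 5)), 0)
  # one fully-mapped read across the locus brings the depth to 5
  fx5 <- tipFixture(seed = 40, m5 = c(60, 70), m3 = c(60, 70),
                    bgStarts = 1950)
  calls <- callTips(fx5$sam, fx5$refSet, fx5$lib, minDepth = 5)
  expect_equal(length(calls), 1)
  expect_equal(calls$depth, 5)
})

test_that("insertion-free alignments yield no calls", {
  set.seed(44)
  ref <- randomSeq(3000)
  sam <- writeSam(vapply(seq(1, 2800, by = 97), function(s)
    bgRead(ref, s), ""), "chr1", 3000)
  lib <- Biostrings::DNAStringSet(c(M1 = makeElement(150, 12)))
  expect_equal(length(callTips(
    sam, Biostrings::DNAStringSet(setNames(ref, "chr1")), lib)), 0)
})

test_that("raising thresholds never increases the number of calls", {
  fx <- tipFixture(seed = 50, m5 = seq(50, 86, by = 4),
                   m3 = seq(52, 88, by = 4), nBg = 5)
  nCalls <- function(...) length(callTips(fx$sam, fx$refSet, fx$lib, ...))
  base <- nCalls()
  expect_true(all(diff(sapply(c(5, 15, 30, 60),
                              function(d) nCalls(minDepth = d))) <= 0))
  expect_true(all(diff(sapply(c(10, 14, 30),
                              function(cl) nCalls(minClip = cl))) <= 0))
  expect_equal(base, 1)
})

test_that("chromosomes absent from the reference are reported by name", {
  fx <- tipFixture(seed = 60)
  wrongRef <- Biostrings::DNAStringSet(setNames(randomSeq(4000), "chrZ"))
  expect_error(callTips(fx$sam, wrongRef, fx$lib), "chr1")
})

test_that("differential loci are a tolerance-aware two-way set difference", {
  mk <- function(starts, width = 3) {
    GenomicRanges::GRanges("chr1", IRanges::IRanges(starts,
                                                    starts + width - 1),
                           locus_id = paste0("L", starts),
                           mite_id = "M1")
  }
  a <- mk(c(1000, 5000))
  b <- mk(5000)
  d <- diffTips(a, b)
  expect_equal(length(d), 1)
  expect_equal(GenomicRanges::start(d), 1000)
  expect_equal(d$direction, "sample_only")
  # self-difference is empty; direction labels are antisymmetric
  expect_equal(length(diffTips(a, a)), 0)
  d2 <- diffTips(b, a)
  expect_equal(d2$direction, "reference_only")
  expect_equal(GenomicRanges::start(d2), 1000)
  # near-identical breakpoints are the same locus within the tolerance
  expect_equal(length(diffTips(mk(1000), mk(1003), locusTol = 5)), 0)
  expect_equal(length(diffTips(mk(1000), mk(1006), locusTol = 5)), 2)
})

test_that("presence reconfirmation distinguishes absent from no-data", {
  fx <- tipFixture(seed = 70, m5 = c(55, 65, 75), m3 = c(55, 65, 75),
                   nBg = 4)
  # a covered sample without clips, and an uncovered sample
  set.seed(70)
  coveredSam <- writeSam(vapply(seq(1900, 2050, by = 30), function(s)
    bgRead(fx$ref, s), ""), "chr1", 4000)
  emptySam <- writeSam(bgRead(fx$ref, 100), "chr1", 4000)
  loci <- callTips(fx$sam, fx$refSet, fx$lib)
  tpm <- reconfirmLoci(loci,
                       c(withTip = fx$sam, covered = coveredSam,
                         uncovered = emptySam),
                       fx$refSet, fx$lib)
  expect_s4_class(tpm, "TipPresenceMatrix")
  expect_equal(unname(presence(tpm)[1, ]),
               c("present", "absent", "no_data"))
  # a stricter support threshold turns single-read support into absence
  tpm2 <- reconfirmLoci(loci, c(withTip = fx$sam), fx$refSet, fx$lib,
                        minSupport = 7)
  expect_equal(unname(presence(tpm2)[1, 1]), "absent")
  expect_error(reconfirmLoci(loci, c(x = "/nonexistent.sam"), fx$refSet,
                             fx$lib), "missing")
})

test_that("treatment-induced loci require presence in treatment and absence in all controls", {
  loci <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(100, 200, 300), width = 3),
                                 locus_id = c("L1", "L2", "L3"),
                                 mite_id = "M1")
  p <- matrix(c("present", "absent", "absent",
                "present", "absent", "present",
                "present", "absent", "no_data"),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("L1", "L2", "L3"), c("s1", "s2", "c1")))
  tpm <- new("TipPresenceMatrix", loci = loci,
             samples = data.frame(sample_id = c("s1", "s2", "c1"),
                                  group = c("space", "space", "control")),
             presence = p)
  si <- spaceInduced(tpm)
  expect_equal(si$locus_id, "L1")   # L2 shared, L3 disqualified by no_data
  # output is always a subset of the input loci
  expect_true(all(si$locus_id %in% loci$locus_id))
  # with controls blank, every treatment-present locus is induced
  p2 <- p; p2[, "c1"] <- "absent"
  tpm2 <- new("TipPresenceMatrix", loci = loci, samples = tipSamples(tpm),
              presence = p2)
  expect_setequal(spaceInduced(tpm2)$locus_id, c("L1", "L2", "L3"))
  expect_error(spaceInduced(tpm, groups = c(s1 = "space")), "without a group")
})
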