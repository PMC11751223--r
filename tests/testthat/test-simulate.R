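miniCfg <- function(seed = 1, ...) simulationConfig("mini", seed = seed, ...)

test_that("simulated genomes have the advertised structure", {
  art <- simulateGenome(miniCfg(2))
  expect_equal(length(art$genome), 1)
  expect_equal(Biostrings::width(art$genome), 200000)
  expect_equal(length(art$genes), 10)
  expect_equal(length(art$mites), 20)
  expect_equal(length(miteSequences(art$mites)), 20)
  # every element starts with its TIR and ends with the reverse complement
  tir <- 15
  seqs <- as.character(miteSequences(art$mites))
  expect_true(all(vapply(seqs, function(s)
    substr(s, 1, tir) == revComp(substring(s, nchar(s) - tir + 1)), TRUE)))
  # elements are embedded verbatim in the reference, flanked by their TSD
  r <- miteRanges(art$mites)
  chrom <- art$genomeStr[["chr1"]]
  for (i in c(1, 7, 20)) {
    s <- GenomicRanges::start(r[i]); e <- GenomicRanges::end(r[i])
    expect_equal(substr(chrom, s, e), unname(seqs[i]))
  }
  # genes and elements never overlap
  expect_equal(length(GenomicRanges::findOverlaps(
    miteRanges(art$mites), art$genes, ignore.strand = TRUE)), 0)
  # regulatory elements all link to a gene within the window
  links <- assignRegulatoryContext(art$mites, art$genes)
  expect_true(all(art$regulatoryMites %in% links$mite_id))
  # chromatin map partitions the chromosome
  expect_equal(sum(GenomicRanges::width(art$chromatin)), 200000)
})

test_that("equal seeds give byte-identical datasets, different seeds differ", {
  d1 <- file.path(tempdir(), "detA"); d2 <- file.path(tempdir(), "detB")
  d3 <- file.path(tempdir(), "detC")
  cfgA <- miniCfg(5, genome = list(nMites = 6L, nGenes = 4L,
                                   chromLength = 60000L))
  unlink(c(d1, d2, d3), recursive = TRUE)
  simulateDataset(cfgA, d1)
  simulateDataset(cfgA, d2)
  cfgB <- miniCfg(6, genome = list(nMites = 6L, nGenes = 4L,
                                   chromLength = 60000L))
  simulateDataset(cfgB, d3)
  files <- list.files(d1, recursive = TRUE)
  h <- function(d) unname(tools::md5sum(file.path(d, files)))
  expect_identical(h(d1), h(d2))
  expect_false(all(h(d1) == h(d3)))
})

test_that("simulated alignments respect junction geometry and SAM validity", {
  cfg <- miniCfg(9)
  art <- simulateGenome(cfg)
  s <- strsplit(art$implants$samples[1], ";")[[1]][1]
  f <- tempfile(fileext = ".sam")
  simulateAlignments(cfg, art, s, f)
  # the whole file round-trips through the Rsamtools SAM/BAM machinery
  bam <- Rsamtools::asBam(f, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  expect_true(file.exists(bam))
  aln <- readSamAlignments(f)
  ev <- extractSoftClips(aln)
  myImplants <- art$implants[vapply(strsplit(art$implants$samples, ";"),
                                    function(x) s %in% x, TRUE), ]
  for (k in seq_len(nrow(myImplants))) {
    site <- myImplants$site[k]; L <- myImplants$tsd_len[k]
    nLeft <- sum(ev$side == "left_clip" & ev$breakpoint == site)
    nRight <- sum(ev$side == "right_clip" &
                    ev$breakpoint == site + L - 1)
    expect_gte(nLeft, 5)
    expect_gte(nRight, 5)
    expect_true(all(nchar(ev$clipped_seq) >= 10))
  }
  # a sample carrying no implants has no clipped primary records
  ctrl <- "SA3-7_F3_control_2"
  imp2 <- art$implants
  imp2$samples <- vapply(strsplit(imp2$samples, ";"), function(x)
    paste(setdiff(x, ctrl), collapse = ";"), "")
  cfg2 <- simulationConfig("mini", seed = 9, implants = imp2)
  art2 <- simulateGenome(cfg2)
  expect_false(any(grepl(ctrl, art2$implants$samples)))
  f2 <- tempfile(fileext = ".sam")
  simulateAlignments(cfg2, art2, ctrl, f2)
  expect_equal(nrow(extractSoftClips(f2)), 0)
})

test_that("reverse-orientation implants emit reverse-complement clips", {
  cfg <- miniCfg(13)
  art <- simulateGenome(cfg)
  imp <- art$implants
  rev <- imp[imp$orientation == "reverse", ][1, ]
  expect_false(is.na(rev$locus_id))
  s <- strsplit(rev$samples, ";")[[1]][1]
  f <- tempfile(fileext = ".sam")
  simulateAlignments(cfg, art, s, f)
  ev <- extractSoftClips(f)
  ev <- ev[ev$side == "right_clip" &
             ev$breakpoint == rev$site + rev$tsd_len - 1, ]
  ins <- revComp(as.character(miteSequences(art$mites)[[rev$mite_id]]))
  expect_gt(nrow(ev), 0)
  expect_true(all(vapply(ev$clipped_seq, function(cp)
    substr(ins, 1, nchar(cp)) == cp, TRUE)))
})

test_that("cytosine reports follow the binomial model around the true level", {
  cfg <- miniCfg(17)
  art <- simulateGenome(cfg)
  truth <- simulateMethylationTruth(cfg, art)
  s <- "SA3-7_F3_space_1"
  cx <- simulateCXReport(cfg, art, truth, s, path = NULL)
  # an element with forced zero methylation reports zero methylated counts
  f <- tempfile()
  data.table::fwrite(cx, f, sep = "\t", col.names = FALSE)
  calls <- readCXReport(f)
  mites <- art$mites
  res <- miteMethylationLevels(mites, calls)
  tl <- truth$levels[res$mite_id, s]
  totals <- vapply(seq_len(length(mites)), function(i) {
    ov <- IRanges::overlapsAny(calls, miteRanges(mites)[i])
    sum(calls$nMeth[ov] + calls$nUnmeth[ov])
  }, 0)
  se <- sqrt(pmax(tl * (1 - tl), 1e-4) / totals)
  expect_true(all(abs(res$level - tl) <= 4 * se))
  # deterministic given the seed
  cx2 <- simulateCXReport(cfg, art, truth, s, path = NULL)
  expect_identical(cx, cx2)
})

test_that("FASTQ export carries every simulated read with its bases and qualities", {
  cfg <- miniCfg(31, genome = list(chromLength = 50000L, nGenes = 3L,
                                   nMites = 4L))
  art <- simulateGenome(cfg)
  f <- tempfile(fileext = ".sam")
  simulateAlignments(cfg, art, cohortSamples(cfg)$sample_id[1], f)
  fq <- tempfile(fileext = ".fq")
  samToFastq(f, fq)
  sam <- readLines(f)
  nRec <- sum(!startsWith(sam, "@"))
  lines <- readLines(fq)
  expect_equal(length(lines), 4 * nRec)
  expect_true(all(startsWith(lines[seq(1, length(lines), by = 4)], "@")))
  # bases round-trip verbatim for the first record
  first <- strsplit(sam[!startsWith(sam, "@")][1], "\t")[[1]]
  expect_equal(lines[2], first[10])
})

test_that("phenotypes track the target element at exactly the configured correlation", {
  for (r in c(1, 0.8)) {
    cfg <- simulationConfig("mini", seed = 23,
                            phenotype = list(rTrue = r))
    art <- simulateGenome(cfg)
    truth <- simulateMethylationTruth(cfg, art)
    ph <- simulatePhenotypes(cfg, truth)
    main <- ph[ph$trait == "plant_height", ]
    lv <- truth$levels[truth$target, main$sample_id]
    expect_equal(unname(cor(main$value, lv)), r)
  }
  expect_equal(sort(unique(simulatePhenotypes(
    simulationConfig("mini", seed = 23),
    simulateMethylationTruth(simulationConfig("mini", seed = 23),
                             simulateGenome(simulationConfig("mini",
                                                             seed = 23))))$trait)),
    c("awn_length", "plant_height", "tiller_number"))
})
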