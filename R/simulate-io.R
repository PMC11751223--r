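# Enumerate cytosines (both strands) of a genome with their context.
# Returns a data.frame(chrom, pos, strand, context, tri, miteIdx) where
# miteIdx indexes into the MiteSet (NA outside elements).
enumerateCytosines <- function(genomeStr, mites) {
  mr <- miteRanges(mites)
  res <- lapply(names(genomeStr), function(ch) {
    s <- genomeStr[[ch]]
    n <- nchar(s)
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    plus <- which(b == "C")
    minus <- which(b == "G")
    ctxPlus <- function(i) {
      n1 <- ifelse(i + 1L <= n, b[pmin(i + 1L, n)], "N")
      n2 <- ifelse(i + 2L <= n, b[pmin(i + 2L, n)], "N")
      ifelse(n1 == "G", "CG", ifelse(n2 == "G", "CHG", "CHH"))
    }
    ctxMinus <- function(i) {
      p1 <- ifelse(i - 1L >= 1L, b[pmax(i - 1L, 1L)], "N")
      p2 <- ifelse(i - 2L >= 1L, b[pmax(i - 2L, 1L)], "N")
      ifelse(p1 == "C", "CG", ifelse(p2 == "C", "CHG", "CHH"))
    }
    data.frame(
      chrom = ch,
      pos = c(plus, minus),
      strand = rep(c("+", "-"), c(length(plus), length(minus))),
      context = c(ctxPlus(plus), ctxMinus(minus)),
      stringsAsFactors = FALSE)
  })
  cy <- do.call(rbind, res)
  cy <- cy[order(cy$chrom, cy$pos, cy$strand), , drop = FALSE]
  pts <- GenomicRanges::GRanges(cy$chrom, IRanges::IRanges(cy$pos, cy$pos))
  ov <- GenomicRanges::findOverlaps(pts, mr, ignore.strand = TRUE,
                                    select = "first")
  cy$miteIdx <- ov
  rownames(cy) <- NULL
  cy
}

#' Simulate a cytosine report for one sample
#'
#' For every cytosine of the reference (both strands), draws a read depth
#' around the configured per-cytosine coverage and a methylated count
#' Binomial(depth, level), where the level is the sample's true per-element
#' level inside MITEs and the background level elsewhere. Written as a
#' Bismark-style CX report (chrom, 1-based pos, strand, methylated count,
#' unmethylated count, context, trinucleotide placeholder).
#'
#' @param config A [SimulationConfig-class].
#' @param art Artifacts from [simulateGenome()].
#' @param truth Output of [simulateMethylationTruth()].
#' @param sampleId Sample to simulate.
#' @param path Output TSV path (NULL to return the table instead).
#' @param cytosines Optional precomputed [enumerateCytosines] table, reused
#'   across samples.
#' @return The path (invisibly) or the table when `path` is NULL.
#' @export
simulateCXReport <- function(config, art, truth, sampleId, path = NULL,
                             cytosines = NULL) {
  samples <- cohortSamples(config)
  si <- match(sampleId, samples$sample_id)
  if (is.na(si)) stop("unknown sample '", sampleId, "'")
  set.seed(childSeed(config@seed, 100L + si))
  cy <- if (is.null(cytosines)) enumerateCytosines(art$genomeStr, art$mites)
        else cytosines
  lev <- rep(config@methylation$background, nrow(cy))
  inMite <- !is.na(cy$miteIdx)
  lev[inMite] <- truth$levels[cy$miteIdx[inMite], si]
  depth <- stats::rpois(nrow(cy), config@sequencing$perCDepth)
  nMeth <- stats::rbinom(nrow(cy), depth, lev)
  out <- data.frame(chrom = cy$chrom, pos = cy$pos, strand = cy$strand,
                    nMeth = nMeth, nUnmeth = depth - nMeth,
                    context = cy$context, tri = cy$context,
                    stringsAsFactors = FALSE)
  if (is.null(path)) return(out)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE,
                     showProgress = FALSE)
  invisible(path)
}

#' Simulate aligned reads for one sample as SAM
#'
#' Emits background reads fully mapped at the configured depth. For each
#' insertion implanted in the sample, reads that would span the whole
#' duplicated target site cannot exist in the donor genome and are replaced
#' by junction reads: right-clipped alignments ending at the last TSD base
#' whose clip is the inserted element's 5' start, and left-clipped
#' alignments starting at the first TSD base whose clip is its 3' end
#' (respecting implant orientation). Clip lengths range from 10 bp up to
#' read length minus the anchor; at least five clipped reads per junction
#' are guaranteed so every implanted locus is callable at the default
#' thresholds. A few reads internal to the insertion are emitted unmapped.
#'
#' @inheritParams simulateCXReport
#' @param path Output SAM path.
#' @return The path, invisibly.
#' @export
simulateAlignments <- function(config, art, sampleId, path) {
  samples <- cohortSamples(config)
  si <- match(sampleId, samples$sample_id)
  if (is.na(si)) stop("unknown sample '", sampleId, "'")
  set.seed(childSeed(config@seed, 200L + si))
  sq <- config@sequencing
  R <- sq$readLength
  qual <- strrep("I", R)
  imp <- art$implants
  mine <- imp[vapply(strsplit(imp$samples, ";", fixed = TRUE),
                     function(s) sampleId %in% s, TRUE), , drop = FALSE]
  badElem <- setdiff(mine$mite_id, names(miteSequences(art$mites)))
  if (length(badElem))
    stop("implant references unknown element(s): ",
         paste(badElem, collapse = ", "))
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             paste0("@SQ\tSN:", names(art$genomeStr), "\tLN:",
                    nchar(art$genomeStr)))
  recs <- list()
  mkRec <- function(qname, flag, rname, pos, mapq, cigar, seq) {
    data.table::data.table(qname = qname, flag = flag, rname = rname,
                           pos = pos, mapq = mapq, cigar = cigar,
                           rnext = "*", pnext = 0L, tlen = 0L, seq = seq,
                           qual = qual)
  }
  for (ch in names(art$genomeStr)) {
    gstr <- art$genomeStr[[ch]]
    len <- nchar(gstr)
    nBg <- round(sq$depth * len / R)
    starts <- sample.int(len - R + 1L, nBg, replace = TRUE)
    impCh <- mine[mine$chrom == ch, , drop = FALSE]
    if (nrow(impCh)) {
      drop <- rep(FALSE, nBg)
      for (k in seq_len(nrow(impCh))) {
        t0 <- impCh$site[k]; L <- impCh$tsd_len[k]
        drop <- drop | (starts <= t0 - 1L & starts + R - 1L >= t0 + L)
      }
      starts <- starts[!drop]
    }
    if (length(starts)) {
      seqs <- substring(gstr, starts, starts + R - 1L)
      recs[[length(recs) + 1L]] <-
        mkRec(paste0("bg_", ch, "_", seq_along(starts)),
              0L, ch, starts, sq$mapq, paste0(R, "M"), seqs)
    }
    for (k in seq_len(nrow(impCh))) {
      t0 <- impCh$site[k]; L <- impCh$tsd_len[k]
      elem <- as.character(miteSequences(art$mites)[[impCh$mite_id[k]]])
      ins <- if (impCh$orientation[k] == "forward") elem else revComp(elem)
      lambda <- sq$depth * (R - 10L - sq$minAnchor + 1L) / R
      for (side in c("five", "three")) {
        nJ <- max(5L, stats::rpois(1L, lambda))
        m <- sample(seq(sq$minAnchor, R - 10L), nJ, replace = TRUE)
        clip <- R - m
        if (side == "five") {
          # right-clipped: mapped part ends on the last TSD base
          pos <- t0 + L - m
          seqs <- paste0(substring(gstr, pos, t0 + L - 1L),
                         substring(ins, 1L, clip))
          cig <- paste0(m, "M", clip, "S")
        } else {
          # left-clipped: mapped part starts on the first TSD base
          pos <- rep(t0, nJ)
          seqs <- paste0(substring(ins, nchar(ins) - clip + 1L,
                                   nchar(ins)),
                         substring(gstr, t0, t0 + m - 1L))
          cig <- paste0(clip, "S", m, "M")
        }
        recs[[length(recs) + 1L]] <-
          mkRec(paste0("j", side, "_", impCh$locus_id[k], "_",
                       seq_len(nJ)),
                0L, ch, pos, sq$mapq, cig, seqs)
      }
      # reads internal to the insertion: unmapped in the reference
      iStarts <- sample.int(max(1L, nchar(ins) - R + 1L), 3L, replace = TRUE)
      recs[[length(recs) + 1L]] <-
        mkRec(paste0("un_", impCh$locus_id[k], "_", 1:3),
              4L, "*", 0L, 0L, "*",
              substring(ins, iStarts,
                        pmin(iStarts + R - 1L, nchar(ins))))
    }
  }
  writeLines(lines, path)
  data.table::fwrite(data.table::rbindlist(recs), path, sep = "\t",
                     col.names = FALSE, append = TRUE, quote = FALSE,
                     showProgress = FALSE)
  invisible(path)
}

#' Export simulated reads as FASTQ
#'
#' Converts a simulated SAM file to FASTQ so the synthetic reads can be run
#' through a real aligner end-to-end instead of consuming the pre-aligned
#' records. All records are exported (mapped, clipped and unmapped alike);
#' base qualities are carried over verbatim.
#'
#' @param samPath SAM file from [simulateAlignments()].
#' @param fastqPath Output FASTQ path.
#' @return The output path, invisibly.
#' @export
samToFastq <- function(samPath, fastqPath) {
  lines <- readLines(samPath)
  recs <- lines[!startsWith(lines, "@")]
  f <- strsplit(recs, "\t", fixed = TRUE)
  out <- unlist(lapply(f, function(x)
    c(paste0("@", x[1]), x[10], "+", x[11])))
  writeLines(out, fastqPath)
  invisible(fastqPath)
}

#' Write a full synthetic dataset to disk
#'
#' Generates every input the analysis consumes: reference genome (FASTA),
#' gene models (GFF3), MITE loci (BED) and element library (FASTA),
#' chromatin-state map (BED), per-sample cytosine reports and SAM
#' alignments, phenotype table, sample sheet, and a truth table (JSON) that
#' records the implanted insertions, the true methylation levels and the
#' phenotype model, enabling implant-and-recover validation.
#'
#' @param config A [SimulationConfig-class].
#' @param dir Output directory (created if needed).
#' @return Invisible list of paths plus the artifacts and truth objects.
#' @export
simulateDataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "cx"), showWarnings = FALSE)
  dir.create(file.path(dir, "sam"), showWarnings = FALSE)
  art <- simulateGenome(config)
  truth <- simulateMethylationTruth(config, art)
  samples <- cohortSamples(config)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.gff3"),
    mites = file.path(dir, "mites.bed"),
    library = file.path(dir, "mite_library.fa"),
    chromatin = file.path(dir, "chromatin.bed"),
    samples = file.path(dir, "samples.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    truth = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(art$genome, paths$genome)
  geneExport <- art$genes
  geneExport$type <- "gene"
  geneExport$ID <- geneExport$gene_id
  rtracklayer::export(geneExport, paths$genes, format = "gff3")
  miteExport <- miteRanges(art$mites)
  miteExport$name <- miteExport$mite_id
  rtracklayer::export(miteExport, paths$mites, format = "bed")
  Biostrings::writeXStringSet(miteSequences(art$mites), paths$library)
  chromExport <- art$chromatin
  chromExport$name <- chromExport$state
  rtracklayer::export(chromExport, paths$chromatin, format = "bed")
  writeTsv(samples, paths$samples)
  writeTsv(simulatePhenotypes(config, truth), paths$phenotypes)
  cy <- enumerateCytosines(art$genomeStr, art$mites)
  paths$cx <- stats::setNames(
    file.path(dir, "cx", paste0(samples$sample_id, ".cx.tsv")),
    samples$sample_id)
  paths$sam <- stats::setNames(
    file.path(dir, "sam", paste0(samples$sample_id, ".sam")),
    samples$sample_id)
  for (s in samples$sample_id) {
    simulateCXReport(config, art, truth, s, paths$cx[[s]], cytosines = cy)
    simulateAlignments(config, art, s, paths$sam[[s]])
  }
  jsonlite::write_json(
    list(seed = config@seed,
         implants = art$implants,
         target_mite = truth$target,
         regulatory_mites = art$regulatoryMites,
         phenotype = config@phenotype[c("trait", "baseline", "slope",
                                        "rTrue", "noiseSd")],
         mite_ids = rownames(truth$levels),
         sample_ids = colnames(truth$levels),
         true_levels = truth$levels),
    paths$truth, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, list(art = art, truth = truth, sampleSheet = samples)))
}

#' Read back a dataset's truth table
#'
#' @param dir Dataset directory written by [simulateDataset()].
#' @return list with implants (data.frame), true level matrix (elements x
#'   samples), target mite and phenotype model.
#' @export
readTruth <- function(dir) {
  tr <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  lev <- tr$true_levels
  dimnames(lev) <- list(tr$mite_ids, tr$sample_ids)
  list(seed = tr$seed, implants = as.data.frame(tr$implants),
       target = tr$target_mite, regulatoryMites = tr$regulatory_mites,
       phenotype = tr$phenotype, levels = lev)
}

#' Simulate cytosine calls for a set of abstract elements
#'
#' Matrix-level counterpart of [simulateCXReport()] for estimator
#' validation: lays `nMites` elements end-to-end on one synthetic
#' chromosome, gives each `nCytosines` cytosines, and draws counts
#' Binomial(Poisson(perCDepth), level).
#'
#' @param levels Numeric vector of true levels, one per element.
#' @param nCytosines Cytosines per element.
#' @param perCDepth Expected per-cytosine depth.
#' @return list(mites = GRanges with mite_id, calls = cytosine GRanges,
#'   totals = per-element informative read counts).
#' @export
simulateCytosineCounts <- function(levels, nCytosines = 50,
                                   perCDepth = 20) {
  nM <- length(levels)
  ids <- sprintf("MITE%04d", seq_len(nM))
  gap <- 10L
  span <- nCytosines + gap
  starts <- (seq_len(nM) - 1L) * span + 1L
  mites <- GenomicRanges::GRanges("sim",
    IRanges::IRanges(starts, starts + nCytosines - 1L), mite_id = ids)
  pos <- rep(starts, each = nCytosines) +
    rep(seq_len(nCytosines) - 1L, nM)
  depth <- stats::rpois(nM * nCytosines, perCDepth)
  nMeth <- stats::rbinom(nM * nCytosines, depth,
                         rep(levels, each = nCytosines))
  calls <- GenomicRanges::GRanges("sim", IRanges::IRanges(pos, pos),
                                  strand = "+",
                                  nMeth = nMeth, nUnmeth = depth - nMeth,
                                  context = "CpG")
  totals <- vapply(split(depth, rep(seq_len(nM), each = nCytosines)),
                   sum, 0)
  list(mites = mites, calls = calls, totals = unname(totals))
}

#' Simulate a methylation-phenotype screening cohort in memory
#'
#' Cohort-level generator for correlation-screen validation: one line
#' across three generations with treated and control replicates (n = 18 by
#' default), `nMites` regulatory elements with per-sample levels estimated
#' from binomial counts, and one designated target element whose true level
#' drives the trait with true correlation `rTrue` (0 for a null cohort
#' where the phenotype is independent of methylation).
#'
#' @param nMites Number of regulatory elements.
#' @param rTrue True methylation-phenotype correlation for the target.
#' @param repsPerGroup Replicates per group per generation.
#' @param generations Generation labels.
#' @param nCytosines,perCDepth Estimation noise model per element.
#' @param targetLevelSd Across-sample sd of the target's true level.
#' @param slope,baseline Phenotype model.
#' @return list(levels = estimated level matrix, phenotypes, links, target,
#'   trueLevels).
#' @export
simulateScreenCohort <- function(nMites = 50, rTrue = 0.8,
                                 repsPerGroup = 3,
                                 generations = c("F3", "F4", "F5"),
                                 nCytosines = 50, perCDepth = 20,
                                 targetLevelSd = 0.15, slope = 30,
                                 baseline = 100) {
  samples <- expand.grid(replicate = seq_len(repsPerGroup),
                         group = c("space", "control"),
                         generation = generations,
                         stringsAsFactors = FALSE)
  sampleIds <- paste("SA3-7", samples$generation, samples$group,
                     samples$replicate, sep = "_")
  nS <- length(sampleIds)
  ids <- sprintf("MITE%04d", seq_len(nMites))
  base <- stats::runif(nMites, 0.2, 0.8)
  true <- matrix(clamp01(base + stats::rnorm(nMites * nS, 0, 0.05)),
                 nMites, nS, dimnames = list(ids, sampleIds))
  target <- ids[1]
  true[target, ] <- clamp01(0.5 + stats::rnorm(nS, 0, targetLevelSd))
  totals <- matrix(pmax(1L, stats::rpois(nMites * nS,
                                         nCytosines * perCDepth)),
                   nMites, nS)
  est <- stats::rbinom(nMites * nS, totals, true) / totals
  est <- matrix(est, nMites, nS, dimnames = dimnames(true))
  tl <- true[target, ]
  value <- if (rTrue > 0) {
    coupleTrait(tl, rTrue, baseline + slope * mean(tl),
                abs(slope) * stats::sd(tl) / rTrue)
  } else {
    baseline + stats::rnorm(nS, 0, abs(slope) * targetLevelSd * 0.75)
  }
  phenotypes <- data.frame(sample_id = sampleIds, trait = "plant_height",
                           value = value, stringsAsFactors = FALSE)
  links <- data.frame(mite_id = ids,
                      gene_id = sprintf("gene%04d", seq_len(nMites)),
                      relation = "upstream", distance = 500L,
                      stringsAsFactors = FALSE)
  list(levels = est, phenotypes = phenotypes, links = links,
       target = target, trueLevels = true)
}
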