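defaultGenome <- function() {
  list(nChroms = 2L, chromLength = 300000L, nGenes = 30L, nMites = 60L,
       miteLengthRange = c(120L, 400L), tirLength = 15L, tsdRange = c(2L, 5L),
       geneLength = 2000L, heterochromatinFrac = 0.3, regulatoryFrac = 0.6,
       tipEuchromatinProb = 0.9)
}

defaultCohort <- function() {
  list(lines = c("SA3-7", "SA6-2", "SC6-6"),
       generations = c("F3", "F4", "F5"), repsPerGroup = 3L)
}

defaultSequencing <- function() {
  list(readLength = 100L, depth = 30, perCDepth = 20, minAnchor = 20L,
       mapq = 60L, errorRate = 0)
}

defaultMethylation <- function() {
  list(background = 0.05, miteLevelRange = c(0.2, 0.8), hyperFrac = 0.25,
       hypoFrac = 0.25, shiftRange = c(0.05, 0.3), replicateSd = 0.02)
}

defaultPhenotype <- function() {
  list(trait = "plant_height", baseline = 100, slope = 30, rTrue = 0.8,
       targetLevelSd = 0.15, noiseSd = NULL,
       otherTraits = c(tiller_number = 15, awn_length = 5))
}

mergeList <- function(base, override) {
  for (k in names(override)) base[[k]] <- override[[k]]
  base
}

#' Build a simulation configuration
#'
#' Assembles a [SimulationConfig-class]. Two presets encode the study
#' designs discussed in the vignette:
#' \describe{
#'   \item{cohort}{the full design: 3 mutagenised lines x generations F3-F5
#'     x (3 treated + 3 control) replicates = 54 samples, on a 2 x 300-kb
#'     genome.}
#'   \item{mini}{a single line and generation (6 samples) on a 1 x 200-kb
#'     genome with 10 genes and 20 MITEs: every analysis stage runs in
#'     seconds.}
#' }
#' Any parameter group can be overridden by passing a partial list; the
#' `implants` table defaults to a per-line scheme of 4 treatment-only plus 2
#' shared insertion loci (10 insertion events per line), generated when the
#' genome is simulated.
#'
#' @param preset `"mini"` or `"cohort"`.
#' @param seed Master seed; fixes every output byte.
#' @param genome,cohort,sequencing,methylation,phenotype Partial lists of
#'   overrides (see [SimulationConfig-class] for the keys).
#' @param implants Optional explicit implant table (line, locus_id, chrom,
#'   site, tsd_len, mite_id, orientation, samples).
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(preset = c("mini", "cohort"), seed = 1,
                             genome = list(), cohort = list(),
                             sequencing = list(), methylation = list(),
                             phenotype = list(), implants = NULL) {
  preset <- match.arg(preset)
  g <- defaultGenome(); co <- defaultCohort()
  if (preset == "mini") {
    g <- mergeList(g, list(nChroms = 1L, chromLength = 200000L,
                           nGenes = 10L, nMites = 20L))
    co <- mergeList(co, list(lines = "SA3-7", generations = "F3"))
  }
  ph <- mergeList(defaultPhenotype(), phenotype)
  if (is.null(ph$noiseSd)) {
    # noise that yields the requested true correlation given the level sd
    ph$noiseSd <- if (ph$rTrue > 0)
      abs(ph$slope) * ph$targetLevelSd * sqrt(1 / ph$rTrue^2 - 1)
    else abs(defaultPhenotype()$slope) * ph$targetLevelSd * 0.75
  }
  new("SimulationConfig",
      seed = as.integer(seed),
      genome = mergeList(g, genome),
      cohort = mergeList(co, cohort),
      sequencing = mergeList(defaultSequencing(), sequencing),
      methylation = mergeList(defaultMethylation(), methylation),
      phenotype = ph,
      implants = if (is.null(implants)) data.frame() else implants)
}

#' Sample sheet implied by a configuration
#'
#' @param config A [SimulationConfig-class].
#' @return data.frame(sample_id, line, generation, group, replicate); ids
#'   are `line_generation_group_replicate`.
#' @export
cohortSamples <- function(config) {
  co <- config@cohort
  df <- expand.grid(replicate = seq_len(co$repsPerGroup),
                    group = c("space", "control"),
                    generation = co$generations, line = co$lines,
                    stringsAsFactors = FALSE)
  df <- df[, c("line", "generation", "group", "replicate")]
  df$sample_id <- paste(df$line, df$generation, df$group, df$replicate,
                        sep = "_")
  df <- df[order(df$line, df$generation, df$group, df$replicate), ,
           drop = FALSE]
  rownames(df) <- NULL
  df[, c("sample_id", "line", "generation", "group", "replicate")]
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Couple a trait to a driver vector x at exactly the requested sample
# correlation (the empirical construction, as in MASS::mvrnorm with
# empirical = TRUE): the noise is orthogonalised against x and mixed with
# weights (rho, sqrt(1 - rho^2)). rho = 0 returns pure independent noise,
# leaving full sampling variation for null calibration.
coupleTrait <- function(x, rho, mu, sigma) {
  n <- length(x)
  if (rho == 0) return(mu + stats::rnorm(n, 0, sigma))
  sx <- stats::sd(x)
  if (sx == 0) stop("cannot couple a trait to a constant driver")
  u <- (x - mean(x)) / sx
  e <- stats::rnorm(n)
  r <- stats::residuals(stats::lm(e ~ x))
  if (stats::sd(r) == 0) r <- stats::rnorm(n)   # degenerate n
  v <- (r - mean(r)) / stats::sd(r)
  mu + sigma * (rho * u + sqrt(1 - rho^2) * v)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Simulate the reference genome and its annotations
#'
#' Generates a random genome carrying non-overlapping genes and MITEs. Each
#' element is built as TIR + core + reverse-complemented TIR and embedded in
#' the reference flanked by its own target-site duplication; a contiguous
#' central fraction of every chromosome is labelled heterochromatin.
#' Candidate insertion sites for non-reference (implanted) copies are drawn
#' away from genes, reference elements and chromosome ends, landing in
#' euchromatin with probability `tipEuchromatinProb`.
#'
#' All draws depend only on `config@seed`, so equal configurations give
#' byte-identical artifacts.
#'
#' @param config A [SimulationConfig-class].
#' @return list(genome = DNAStringSet, genomeStr = named character, genes =
#'   GRanges, mites = [MiteSet-class], chromatin = GRanges, implants =
#'   data.frame, regulatoryMites = character vector of mite ids placed in
#'   gene regulatory windows).
#' @export
simulateGenome <- function(config) {
  validObject(config)
  g <- config@genome; sq <- config@sequencing
  set.seed(childSeed(config@seed, 1L))
  chroms <- paste0("chr", seq_len(g$nChroms))
  genomeStr <- vapply(chroms, function(ch) randomDna(g$chromLength), "")
  perChromGenes <- tabulate(rep(seq_len(g$nChroms),
                                length.out = g$nGenes), g$nChroms)
  # deterministic slot layout: one gene centred per slot; regulatory MITEs
  # go into its 2-kb flanks, intergenic MITEs near the slot boundary
  genes <- list(); mites <- list()
  nReg <- round(g$regulatoryFrac * g$nMites)
  miteLens <- sample(seq(g$miteLengthRange[1], g$miteLengthRange[2]),
                     g$nMites, replace = TRUE)
  miteCount <- 0L
  geneCount <- 0L
  miteRows <- list()
  for (ci in seq_len(g$nChroms)) {
    ng <- perChromGenes[ci]
    if (ng == 0) next
    slot <- floor(g$chromLength / ng)
    if (slot < g$geneLength + 9000)
      stop("chromosome too short for the requested genes")
    for (k in seq_len(ng)) {
      geneCount <- geneCount + 1L
      s <- (k - 1L) * slot + floor(slot / 2)
      genes[[geneCount]] <- data.frame(
        chrom = chroms[ci], start = s, end = s + g$geneLength - 1L,
        strand = sample(c("+", "-"), 1L),
        gene_id = sprintf("gene%03d", geneCount))
    }
  }
  genes <- do.call(rbind, genes)
  # regulatory MITEs: round-robin over genes, first filling every upstream
  # flank and then every downstream flank, so no gene flank hosts two
  # elements and placements can never collide
  if (nReg > 2L * nrow(genes))
    stop("regulatoryFrac * nMites may not exceed twice the gene count")
  regGene <- rep(seq_len(nrow(genes)), length.out = nReg)
  flankSide <- ifelse(seq_len(nReg) <= nrow(genes), "up", "down")
  regulatoryIds <- character()
  intergenicIdx <- 0L
  for (i in seq_len(g$nMites)) {
    len <- miteLens[i]
    id <- sprintf("MITE%03d", i)
    if (i <= nReg) {
      gi <- regGene[i]
      gap <- sample(50:1500, 1L)
      if (flankSide[i] == "up") {
        e <- genes$start[gi] - gap - 1L
        s <- e - len + 1L
      } else {
        s <- genes$end[gi] + gap + 1L
        e <- s + len - 1L
      }
      ch <- genes$chrom[gi]
      regulatoryIds <- c(regulatoryIds, id)
    } else {
      # intergenic: tiled near slot boundaries, several kb from the
      # slot-centred genes; deterministic tiling keeps them disjoint
      ci <- ((i - 1L) %% g$nChroms) + 1L
      ng <- perChromGenes[ci]
      slot <- floor(g$chromLength / ng)
      j <- intergenicIdx %/% g$nChroms
      intergenicIdx <- intergenicIdx + 1L
      k <- (j %% ng) + 1L
      off <- 200L + (j %/% ng) * 1200L
      if (off + len > slot %/% 2L - 3000L)
        stop("too many intergenic MITEs for the slot layout")
      s <- (k - 1L) * slot + off
      e <- s + len - 1L
      ch <- chroms[ci]
    }
    miteRows[[i]] <- data.frame(chrom = ch, start = s, end = e,
                                mite_id = id, stringsAsFactors = FALSE)
  }
  miteDf <- do.call(rbind, miteRows)
  stopifnot(all(miteDf$start > g$tsdRange[2]),
            all(miteDf$end + g$tsdRange[2] <= g$chromLength))
  # element sequences: TIR + core + revcomp(TIR), embedded with a TSD on
  # both reference flanks
  elemSeqs <- character(g$nMites)
  for (i in seq_len(g$nMites)) {
    len <- miteDf$end[i] - miteDf$start[i] + 1L
    tir <- randomDna(g$tirLength)
    core <- randomDna(len - 2L * g$tirLength)
    elem <- paste0(tir, core, revComp(tir))
    elemSeqs[i] <- elem
    tsdLen <- sample(seq(g$tsdRange[1], g$tsdRange[2]), 1L)
    tsd <- randomDna(tsdLen)
    ch <- miteDf$chrom[i]
    str <- genomeStr[[ch]]
    substr(str, miteDf$start[i], miteDf$end[i]) <- elem
    substr(str, miteDf$start[i] - tsdLen, miteDf$start[i] - 1L) <- tsd
    substr(str, miteDf$end[i] + 1L, miteDf$end[i] + tsdLen) <- tsd
    genomeStr[[ch]] <- str
  }
  geneGr <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(genes$start, genes$end),
                                   strand = genes$strand,
                                   gene_id = genes$gene_id)
  miteGr <- GenomicRanges::GRanges(
    miteDf$chrom, IRanges::IRanges(miteDf$start, miteDf$end), strand = "*",
    mite_id = miteDf$mite_id, family = "synthetic",
    tir_len = g$tirLength)
  seqs <- Biostrings::DNAStringSet(elemSeqs)
  names(seqs) <- miteDf$mite_id
  miteSet <- MiteSet(miteGr, seqs)
  # chromatin: contiguous central heterochromatin block per chromosome
  hw <- round(g$heterochromatinFrac * g$chromLength)
  hs <- round((g$chromLength - hw) / 2)
  chromatin <- do.call(c, lapply(chroms, function(ch)
    GenomicRanges::GRanges(ch,
      IRanges::IRanges(c(1L, hs + 1L, hs + hw + 1L),
                       c(hs, hs + hw, g$chromLength)),
      state = c("euchromatin", "heterochromatin", "euchromatin"))))
  implants <- if (nrow(config@implants)) config@implants else
    defaultImplants(config, chroms, miteDf, genes, hs, hw)
  list(genome = Biostrings::DNAStringSet(genomeStr),
       genomeStr = genomeStr, genes = geneGr, mites = miteSet,
       chromatin = chromatin, implants = implants,
       regulatoryMites = regulatoryIds)
}

# Default implanted-insertion scheme: per line, 4 treatment-only loci plus 2
# loci shared with controls (10 insertion events per line). Sites avoid
# genes, reference elements and each other; ~tipEuchromatinProb of them land
# in euchromatin.
defaultImplants <- function(config, chroms, miteDf, genes, hs, hw) {
  g <- config@genome; sq <- config@sequencing
  samples <- cohortSamples(config)
  rows <- list()
  occupied <- rbind(
    data.frame(chrom = miteDf$chrom, start = miteDf$start - 1000L,
               end = miteDf$end + 1000L),
    data.frame(chrom = genes$chrom, start = genes$start - 200L,
               end = genes$end + 200L))
  pickSite <- function() {
    for (try in 1:500) {
      ch <- sample(chroms, 1L)
      inEu <- stats::runif(1) < g$tipEuchromatinProb
      rng <- if (inEu) {
        if (stats::runif(1) < 0.5) c(sq$readLength + 10L, hs - 200L)
        else c(hs + hw + 200L, g$chromLength - sq$readLength - 10L)
      } else c(hs + 200L, hs + hw - 200L)
      site <- sample(seq(rng[1], rng[2]), 1L)
      occ <- occupied[occupied$chrom == ch, , drop = FALSE]
      if (nrow(occ) == 0 ||
          all(site + 20L < occ$start | site - 20L > occ$end)) {
        occupied <<- rbind(occupied,
          data.frame(chrom = ch, start = site - 3L * sq$readLength,
                     end = site + 3L * sq$readLength))
        return(list(chrom = ch, site = site))
      }
    }
    stop("could not place implant sites: genome too crowded")
  }
  for (line in config@cohort$lines) {
    sl <- samples[samples$line == line, , drop = FALSE]
    spaceIds <- function(reps, gen = NULL) {
      d <- sl[sl$group == "space" & sl$replicate %in% reps, , drop = FALSE]
      if (!is.null(gen)) d <- d[d$generation %in% gen, , drop = FALSE]
      d$sample_id
    }
    ctrlIds <- function(reps) {
      sl$sample_id[sl$group == "control" & sl$replicate %in% reps]
    }
    assign <- list(
      list(tag = "spaceonly1", who = spaceIds(1)),
      list(tag = "spaceonly2", who = spaceIds(2)),
      list(tag = "spaceonly3", who = spaceIds(3)),
      list(tag = "spaceonly4", who = spaceIds(c(1, 2))),
      list(tag = "shared1", who = c(spaceIds(1), ctrlIds(1))),
      list(tag = "shared2", who = c(spaceIds(2), ctrlIds(c(2, 3)))))
    for (a in assign) {
      loc <- pickSite()
      tsdLen <- sample(seq(g$tsdRange[1], g$tsdRange[2]), 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        line = line,
        locus_id = paste0(line, "_", a$tag),
        chrom = loc$chrom, site = loc$site, tsd_len = tsdLen,
        mite_id = sample(miteDf$mite_id, 1L),
        orientation = sample(c("forward", "reverse"), 1L),
        samples = paste(a$who, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' True per-MITE methylation levels per sample
#'
#' Draws a base level per element, then applies line-specific hyper- or
#' hypomethylation shifts to treated samples (a fixed fraction of elements
#' shifts up, another down, with per-replicate jitter). One regulatory
#' element is designated the phenotype target; its level varies across all
#' samples with standard deviation `targetLevelSd` so that the
#' methylation-phenotype coupling has signal to work with.
#'
#' @param config A [SimulationConfig-class].
#' @param art Artifact list from [simulateGenome()].
#' @return list(levels = matrix elements x samples, target = target mite
#'   id).
#' @export
simulateMethylationTruth <- function(config, art) {
  set.seed(childSeed(config@seed, 3L))
  m <- config@methylation
  samples <- cohortSamples(config)
  ids <- miteIds(art$mites)
  nM <- length(ids)
  base <- stats::runif(nM, m$miteLevelRange[1], m$miteLevelRange[2])
  target <- if (length(art$regulatoryMites)) art$regulatoryMites[1] else
    ids[1]
  ti <- match(target, ids)
  lev <- matrix(NA_real_, nM, nrow(samples),
                dimnames = list(ids, samples$sample_id))
  for (line in unique(samples$line)) {
    pool <- setdiff(seq_len(nM), ti)
    hyper <- sample(pool, round(m$hyperFrac * nM))
    hypo <- sample(setdiff(pool, hyper), round(m$hypoFrac * nM))
    shift <- stats::runif(nM, m$shiftRange[1], m$shiftRange[2])
    for (si in which(samples$line == line)) {
      x <- base
      if (samples$group[si] == "space") {
        x[hyper] <- x[hyper] + shift[hyper]
        x[hypo] <- x[hypo] - shift[hypo]
      }
      x <- x + stats::rnorm(nM, 0, m$replicateSd)
      x[ti] <- 0.5 + stats::rnorm(1, 0, config@phenotype$targetLevelSd)
      lev[, si] <- clamp01(x)
    }
  }
  list(levels = lev, target = target)
}

#' Phenotype table coupled to the target element's methylation
#'
#' The configured trait follows the linear model
#' `baseline + slope * level(target) + noise`, constructed so that the
#' realised sample correlation between the target's true levels and the
#' trait equals `rTrue` exactly (noise orthogonalised against the levels
#' and mixed with weights rho and sqrt(1 - rho^2); `rTrue = 0` draws fully
#' independent noise instead). The remaining traits are independent noise
#' around their baselines.
#'
#' @param config A [SimulationConfig-class].
#' @param truth Output of [simulateMethylationTruth()].
#' @return Long data.frame(sample_id, line, generation, group, replicate,
#'   trait, value).
#' @export
simulatePhenotypes <- function(config, truth) {
  set.seed(childSeed(config@seed, 4L))
  ph <- config@phenotype
  samples <- cohortSamples(config)
  if (!truth$target %in% rownames(truth$levels))
    stop("target element '", truth$target, "' absent from the truth matrix")
  tl <- truth$levels[truth$target, samples$sample_id]
  value <- if (ph$rTrue > 0) {
    # trait sd implied by the population model at correlation rTrue
    coupleTrait(tl, ph$rTrue, ph$baseline + ph$slope * mean(tl),
                abs(ph$slope) * stats::sd(tl) / ph$rTrue)
  } else {
    ph$baseline + stats::rnorm(nrow(samples), 0, ph$noiseSd)
  }
  main <- data.frame(samples, trait = ph$trait, value = value)
  others <- lapply(names(ph$otherTraits), function(tr)
    data.frame(samples, trait = tr,
               value = ph$otherTraits[[tr]] *
                 (1 + stats::rnorm(nrow(samples), 0, 0.1))))
  out <- rbind(main, do.call(rbind, others))
  rownames(out) <- NULL
  out
}
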