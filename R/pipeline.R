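writeManifest <- function(dir, stage, params, inputs = character(),
                          outputs = character()) {
  man <- list(
    tool = "mitescan",
    version = as.character(utils::packageVersion("mitescan")),
    stage = stage,
    timestamp = format(Sys.time(), tz = "UTC"),
    params = params,
    input_digests = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    output_digests = as.list(tools::md5sum(outputs[file.exists(outputs)])))
  jsonlite::write_json(man, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(man)
}

#' Generate a synthetic dataset with a run manifest
#'
#' Wraps [simulateDataset()] and records a manifest (tool version,
#' parameters, seed, file digests). Reruns with an equal configuration
#' produce identical content digests; only the manifest timestamp differs.
#'
#' @param config A [SimulationConfig-class].
#' @param outDir Output directory.
#' @param overwrite Re-generate even if the directory already holds a
#'   dataset.
#' @return Invisible list of dataset paths (see [simulateDataset()]).
#' @export
runSimulate <- function(config, outDir, overwrite = FALSE) {
  if (file.exists(file.path(outDir, "truth.json")) && !overwrite) {
    msg("dataset already present in ", outDir, "; skipping (overwrite=FALSE)")
    return(invisible(NULL))
  }
  res <- simulateDataset(config, outDir)
  outs <- unlist(res[c("genome", "genes", "mites", "library", "chromatin",
                       "samples", "phenotypes", "truth", "cx", "sam")],
                 use.names = FALSE)
  writeManifest(outDir, "simulate",
                params = list(seed = config@seed, genome = config@genome,
                              cohort = config@cohort,
                              sequencing = config@sequencing,
                              methylation = config@methylation,
                              phenotype = config@phenotype),
                outputs = outs)
  invisible(res)
}

pipelineInputs <- function(datasetDir) {
  samples <- readTsv(file.path(datasetDir, "samples.tsv"))
  list(
    samples = samples,
    genome = file.path(datasetDir, "genome.fa"),
    genes = file.path(datasetDir, "genes.gff3"),
    mites = file.path(datasetDir, "mites.bed"),
    library = file.path(datasetDir, "mite_library.fa"),
    chromatin = file.path(datasetDir, "chromatin.bed"),
    phenotypes = file.path(datasetDir, "phenotypes.tsv"),
    cx = stats::setNames(file.path(datasetDir, "cx",
                                   paste0(samples$sample_id, ".cx.tsv")),
                         samples$sample_id),
    sam = stats::setNames(file.path(datasetDir, "sam",
                                    paste0(samples$sample_id, ".sam")),
                          samples$sample_id))
}

# space sample -> its matched controls (same line and generation)
matchedControls <- function(samples, sampleId) {
  s <- samples[samples$sample_id == sampleId, ]
  samples$sample_id[samples$group == "control" & samples$line == s$line &
                      samples$generation == s$generation]
}

#' Run the analysis pipeline on a simulated or assembled dataset
#'
#' Executes the selected stages against a dataset directory laid out as by
#' [simulateDataset()] and writes plain TSV/BED outputs plus a manifest to
#' `outDir`. Stages are independent and resumable: outputs that already
#' exist are not recomputed unless `overwrite = TRUE`.
#'
#' \describe{
#'   \item{methylation}{per-element level matrix across samples;
#'     differential methylation of every treated sample against the mean of
#'     its matched controls; hyper/hypo proportions (regulatory elements
#'     only) and their per-generation stability SDs.}
#'   \item{tips}{per-sample TIP calls; differential loci of every treated
#'     sample against every matched control; reconfirmation of the merged
#'     locus list across all samples; treatment-induced loci.}
#'   \item{association}{Pearson screen of regulatory-element methylation
#'     against the phenotype per line; chromatin fraction and 1-Mb bin
#'     counts of the treatment-induced loci; neighbour genes of each.}
#' }
#'
#' @param datasetDir Dataset directory.
#' @param outDir Results directory (created).
#' @param stages Subset of c("methylation", "tips", "association");
#'   association requires the other two stages' outputs (computed in the
#'   same call if selected).
#' @param trait Phenotype screened in the association stage.
#' @param window Regulatory window in bp.
#' @param minClip,minDepth,clusterTol,tsdRange,locusTol TIP thresholds (see
#'   [callTips()]).
#' @param alpha,rMin Correlation screen thresholds.
#' @param binSize Hotspot bin width in bp.
#' @param overwrite Recompute existing outputs.
#' @return Invisible named list of output paths.
#' @export
runPipeline <- function(datasetDir, outDir,
                        stages = c("methylation", "tips", "association"),
                        trait = "plant_height", window = 2000,
                        minClip = 10, minDepth = 5, clusterTol = 3,
                        tsdRange = c(2, 10), locusTol = 5,
                        alpha = 0.05, rMin = 0.65, binSize = 1e6,
                        overwrite = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  inp <- pipelineInputs(datasetDir)
  need <- c(inp$genome, inp$genes, inp$mites, inp$library)
  if ("methylation" %in% stages) need <- c(need, inp$cx)
  if ("tips" %in% stages) need <- c(need, inp$sam)
  if ("association" %in% stages)
    need <- c(need, inp$phenotypes, inp$chromatin)
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("missing dataset input(s): ", paste(missing, collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  samples <- inp$samples
  mites <- loadMiteAnnotations(inp$mites, inp$library)
  genes <- loadGeneModels(inp$genes)
  links <- assignRegulatoryContext(mites, genes, window = window)
  out <- list()
  done <- function(p) all(file.exists(p)) && !overwrite

  if ("methylation" %in% stages) {
    out$levels <- file.path(outDir, "methylation_levels.tsv")
    out$differential <- file.path(outDir, "differential_methylation.tsv")
    out$stability <- file.path(outDir, "stability.tsv")
    out$links <- file.path(outDir, "regulatory_links.tsv")
    if (done(c(out$levels, out$differential, out$stability, out$links))) {
      msg("methylation outputs present; skipping stage")
    } else {
      se <- methylationMatrix(mites, inp$cx, sampleInfo = samples)
      lev <- SummarizedExperiment::assay(se, "level")
      writeTsv(data.frame(mite_id = rownames(lev), lev,
                          check.names = FALSE),
               out$levels, comments = "per-MITE methylation level (weighted)")
      writeTsv(links, out$links,
               comments = sprintf("MITE-gene links, window %d bp", window))
      spaceIds <- samples$sample_id[samples$group == "space"]
      regIds <- intersect(unique(links$mite_id), rownames(lev))
      diffRows <- lapply(spaceIds, function(s) {
        ctrl <- matchedControls(samples, s)
        d <- differentialMethylation(lev[regIds, s],
                                     lev[regIds, ctrl, drop = FALSE])
        cbind(mite_id = regIds, sample_id = s, d)
      })
      diffDf <- do.call(rbind, diffRows)
      writeTsv(diffDf, out$differential,
               comments = "delta = space level - mean(matched controls)")
      deltaMat <- matrix(diffDf$delta, nrow = length(regIds),
                         dimnames = list(regIds, spaceIds))
      rep <- stabilityReport(deltaMat,
                             samples[match(spaceIds, samples$sample_id), ])
      writeTsv(merge(rep$perSample, rep$perGeneration,
                     by = c("line", "generation"), sort = TRUE),
               out$stability,
               comments = "hyper/hypo proportions per treated sample; SD across replicates")
    }
  }

  if ("tips" %in% stages) {
    tipDir <- file.path(outDir, "tips")
    dir.create(tipDir, showWarnings = FALSE)
    out$tipBeds <- stats::setNames(
      file.path(tipDir, paste0(samples$sample_id, ".bed")),
      samples$sample_id)
    out$presence <- file.path(outDir, "presence_matrix.tsv")
    out$spaceInduced <- file.path(outDir, "space_induced.bed")
    if (done(c(out$tipBeds, out$presence, out$spaceInduced))) {
      msg("TIP outputs present; skipping stage")
    } else {
      ref <- asGenome(inp$genome)
      lib <- readMiteLibrary(inp$library)
      calls <- lapply(samples$sample_id, function(s) {
        cl <- callTips(inp$sam[[s]], ref, lib, minClip = minClip,
                       minDepth = minDepth, clusterTol = clusterTol,
                       tsdRange = tsdRange, sample = s)
        writeTipBed(cl, out$tipBeds[[s]])
        cl
      })
      names(calls) <- samples$sample_id
      # deterministic all-pairs differencing within line x generation
      diffs <- list()
      for (s in samples$sample_id[samples$group == "space"]) {
        for (ctrl in matchedControls(samples, s)) {
          d <- diffTips(calls[[s]], calls[[ctrl]], locusTol = locusTol)
          if (length(d)) diffs[[length(diffs) + 1L]] <- d
        }
      }
      loci <- if (length(diffs))
        dedupeLoci(suppressWarnings(do.call(c, diffs)), locusTol = locusTol)
      else GenomicRanges::GRanges()
      if (length(loci)) {
        tpm <- reconfirmLoci(loci, inp$sam, ref, lib, locusTol = locusTol,
                             minClip = minClip, sampleInfo = samples)
        p <- presence(tpm)
        writeTsv(data.frame(locus_id = rownames(p),
                            chrom = as.character(
                              GenomeInfoDb::seqnames(tipLoci(tpm))),
                            start = GenomicRanges::start(tipLoci(tpm)),
                            end = GenomicRanges::end(tipLoci(tpm)),
                            mite_id = tipLoci(tpm)$mite_id, p,
                            check.names = FALSE),
                 out$presence, comments = "TIP presence calls per sample")
        si <- spaceInduced(tpm)
        writeTipBed(si, out$spaceInduced)
        out$.spaceInducedLoci <- si
      } else {
        writeTsv(data.frame(locus_id = character()), out$presence)
        file.create(out$spaceInduced)
        out$.spaceInducedLoci <- GenomicRanges::GRanges()
      }
    }
  }

  if ("association" %in% stages) {
    out$hits <- file.path(outDir, "correlation_hits.tsv")
    out$bins <- file.path(outDir, "bin_counts.tsv")
    out$chromatin <- file.path(outDir, "chromatin_fraction.tsv")
    out$neighbors <- file.path(outDir, "tip_neighbor_genes.tsv")
    if (done(c(out$hits, out$bins, out$chromatin, out$neighbors))) {
      msg("association outputs present; skipping stage")
    } else {
      levPath <- file.path(outDir, "methylation_levels.tsv")
      if (!file.exists(levPath))
        stop("association stage requires the methylation stage outputs ",
             "(methylation_levels.tsv not found in ", outDir, ")")
      lev <- readTsv(levPath)
      if (nrow(lev) == 0) stop("methylation level matrix is empty")
      levM <- as.matrix(lev[, -1, drop = FALSE])
      rownames(levM) <- lev$mite_id
      phen <- readTsv(inp$phenotypes)
      hits <- do.call(rbind, lapply(unique(samples$line), function(ln) {
        ids <- samples$sample_id[samples$line == ln]
        h <- screenMitePhenotype(levM[, ids, drop = FALSE], phen, links,
                                 trait, alpha = alpha, rMin = rMin)
        if (nrow(h)) cbind(line = ln, h) else NULL
      }))
      if (is.null(hits)) hits <- data.frame()
      writeTsv(hits, out$hits,
               comments = sprintf(
                 "Pearson screen, trait=%s, alpha=%g, rMin=%g, pooled space+control per line",
                 trait, alpha, rMin))
      si <- out$.spaceInducedLoci
      if (is.null(si)) {
        sib <- file.path(outDir, "space_induced.bed")
        si <- if (file.exists(sib) && file.size(sib) > 0)
          rtracklayer::import(sib, format = "bed",
                              extraCols = c(tsd_seq = "character",
                                            mite_id = "character"))
        else GenomicRanges::GRanges()
        if (length(si) && is.null(si$locus_id)) si$locus_id <- si$name
      }
      chromMap <- loadChromatinMap(inp$chromatin)
      genomeSizes <- Biostrings::fasta.seqlengths(inp$genome)
      names(genomeSizes) <- sub("\\s.*$", "", names(genomeSizes))
      if (length(si)) {
        cf <- chromatinFraction(si, chromMap)
        writeTsv(data.frame(fraction_euchromatin = cf$fraction,
                            n_euchromatin = cf$n_euchromatin,
                            n_heterochromatin = cf$n_heterochromatin,
                            n_gap = cf$n_gap),
                 out$chromatin)
        writeTsv(binCounts(si, genomeSizes, binSize = binSize), out$bins,
                 comments = sprintf("bin size %d bp", as.integer(binSize)))
        writeTsv(neighborGeneSets(si, genes), out$neighbors)
      } else {
        writeTsv(data.frame(fraction_euchromatin = NA_real_,
                            n_euchromatin = 0L, n_heterochromatin = 0L,
                            n_gap = 0L), out$chromatin)
        writeTsv(binCounts(GenomicRanges::GRanges(), genomeSizes,
                           binSize = binSize), out$bins)
        writeTsv(data.frame(locus_id = character(),
                            gene_id = character()), out$neighbors)
      }
    }
  }
  out$.spaceInducedLoci <- NULL
  writeManifest(outDir, paste(stages, collapse = "+"),
                params = list(trait = trait, window = window,
                              minClip = minClip, minDepth = minDepth,
                              clusterTol = clusterTol, tsdRange = tsdRange,
                              locusTol = locusTol, alpha = alpha,
                              rMin = rMin, binSize = binSize),
                inputs = need, outputs = unlist(out, use.names = FALSE))
  invisible(out)
}
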