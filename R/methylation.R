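#' Read a cytosine-resolution methylation report
#'
#' Parses a Bismark-style CX report: one row per cytosine with tab-separated
#' columns (chrom, 1-based position, strand, methylated count, unmethylated
#' count, context, trinucleotide context). Rows are returned in file order as
#' a GRanges of width-1 positions; context labels `CG` are normalised to
#' `CpG`.
#'
#' @param path Path to the report (TSV, no header).
#' @return GRanges with metadata columns nMeth, nUnmeth, context.
#' @export
readCXReport <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0)
    return(GenomicRanges::GRanges(nMeth = integer(), nUnmeth = integer(),
                                  context = character()))
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          colClasses = list(character = c(1, 3, 6, 7)),
                          data.table = TRUE, showProgress = FALSE)
  if (nrow(dt) == 0)
    return(GenomicRanges::GRanges(nMeth = integer(), nUnmeth = integer(),
                                  context = character()))
  if (ncol(dt) < 6)
    stop("CX report '", path, "' has fewer than 6 columns")
  asNum <- function(x) suppressWarnings(as.numeric(as.character(x)))
  pos <- asNum(dt[[2]]); nm <- asNum(dt[[4]]); nu <- asNum(dt[[5]])
  bad <- which(!is.finite(pos) | !is.finite(nm) | !is.finite(nu) |
                 pos != floor(pos) | nm != floor(nm) | nu != floor(nu))
  if (length(bad))
    stop("CX report '", path, "': non-integer position or count at line ",
         bad[1])
  ctx <- dt[[6]]
  ctx[ctx == "CG"] <- "CpG"
  gr <- GenomicRanges::GRanges(
    dt[[1]], IRanges::IRanges(as.integer(pos), width = 1L),
    strand = dt[[3]],
    nMeth = as.integer(nm), nUnmeth = as.integer(nu), context = ctx)
  gr
}

#' Per-MITE methylation level
#'
#' Computes the methylation level of each MITE from cytosine calls falling
#' inside the element interval (both strands, all requested contexts).
#' Two estimators are available:
#' \describe{
#'   \item{weighted}{read-count ratio: sum of methylated read counts over the
#'     sum of all informative read counts (the default; equivalent to the
#'     depth-weighted mean of per-position methylated fractions).}
#'   \item{positional}{fraction of covered cytosine positions whose
#'     methylated fraction is at least `positionalCallFrac`.}
#' }
#' Elements with no informative cytosine get `NA` (undefined), never 0.
#'
#' @param mites [MiteSet-class] or GRanges with `mite_id`.
#' @param calls GRanges of cytosine calls from [readCXReport()].
#' @param mode `"weighted"` or `"positional"`.
#' @param minDepthPerC Minimum reads at a cytosine for it to be informative.
#' @param positionalCallFrac Methylated-fraction threshold for calling a
#'   position methylated in positional mode.
#' @param contexts Cytosine contexts to pool (default all three).
#' @return data.frame(mite_id, level, covered_c) where `covered_c` counts
#'   informative cytosines; level is NA iff covered_c is 0.
#' @export
miteMethylationLevels <- function(mites, calls, mode = c("weighted",
                                                         "positional"),
                                  minDepthPerC = 1, positionalCallFrac = 0.5,
                                  contexts = c("CpG", "CHG", "CHH")) {
  mode <- match.arg(mode)
  mr <- if (is(mites, "MiteSet")) miteRanges(mites) else mites
  ids <- S4Vectors::mcols(mr)$mite_id
  depth <- calls$nMeth + calls$nUnmeth
  keep <- depth >= minDepthPerC & calls$context %in% contexts
  ov <- GenomicRanges::findOverlaps(calls[keep], mr, ignore.strand = TRUE)
  lev <- rep(NA_real_, length(mr))
  cov <- integer(length(mr))
  if (length(ov)) {
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    nm <- calls$nMeth[keep][q]
    nu <- calls$nUnmeth[keep][q]
    cov <- as.integer(tabulate(s, nbins = length(mr)))
    if (mode == "weighted") {
      num <- vapply(split(nm, factor(s, levels = seq_along(mr))), sum, 0)
      den <- vapply(split(nm + nu, factor(s, levels = seq_along(mr))), sum, 0)
      lev <- ifelse(den > 0, num / den, NA_real_)
    } else {
      isMeth <- as.numeric(nm / (nm + nu) >= positionalCallFrac)
      called <- vapply(split(isMeth, factor(s, levels = seq_along(mr))),
                       sum, 0)
      lev <- ifelse(cov > 0, called / cov, NA_real_)
    }
  }
  data.frame(mite_id = ids, level = as.numeric(lev),
             covered_c = cov, stringsAsFactors = FALSE)
}

#' Per-sample methylation matrix as a SummarizedExperiment
#'
#' Runs [miteMethylationLevels()] on one CX report per sample and assembles
#' the results into a [SummarizedExperiment::SummarizedExperiment] with
#' assays `level` (in [0,1], NA where uncovered) and `covered` (informative
#' cytosine counts), rowRanges = the MITE loci and colData = sample metadata.
#'
#' @param mites [MiteSet-class].
#' @param cxFiles Named character vector of CX report paths; names are sample
#'   ids.
#' @param sampleInfo data.frame of sample metadata with a `sample_id` column
#'   matching `names(cxFiles)` (optional).
#' @param ... Passed to [miteMethylationLevels()].
#' @return SummarizedExperiment (MITEs x samples).
#' @export
methylationMatrix <- function(mites, cxFiles, sampleInfo = NULL, ...) {
  stopifnot(length(cxFiles) > 0, !is.null(names(cxFiles)))
  mr <- miteRanges(mites)
  lev <- cov <- matrix(NA_real_, length(mr), length(cxFiles),
                       dimnames = list(miteIds(mites), names(cxFiles)))
  for (i in seq_along(cxFiles)) {
    calls <- readCXReport(cxFiles[[i]])
    res <- miteMethylationLevels(mites, calls, ...)
    lev[, i] <- res$level
    cov[, i] <- res$covered_c
  }
  cd <- if (is.null(sampleInfo)) {
    S4Vectors::DataFrame(sample_id = names(cxFiles),
                         row.names = names(cxFiles))
  } else {
    stopifnot(all(names(cxFiles) %in% sampleInfo$sample_id))
    S4Vectors::DataFrame(
      sampleInfo[match(names(cxFiles), sampleInfo$sample_id), , drop = FALSE],
      row.names = names(cxFiles))
  }
  names(mr) <- miteIds(mites)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(level = lev, covered = cov),
    rowRanges = mr, colData = cd)
}

#' Differential methylation against control lines
#'
#' For each element, the difference between a treated sample's methylation
#' level and the mean level of its matched control samples (the control
#' baseline; typically n = 3 control lines).
#'
#' @param spaceLevel Numeric vector of levels in the treated sample (one per
#'   element), or a single level.
#' @param controlLevels Numeric vector (single element) or matrix (elements x
#'   control samples) of control levels.
#' @return data.frame(delta, space_level, control_mean, n_controls); delta is
#'   `space_level - control_mean`, in [-1, 1].
#' @export
differentialMethylation <- function(spaceLevel, controlLevels) {
  if (is.null(controlLevels) || length(controlLevels) == 0)
    stop("no control levels supplied; the control baseline is required")
  if (is.matrix(controlLevels)) {
    stopifnot(nrow(controlLevels) == length(spaceLevel))
    cm <- rowMeans(controlLevels)
    n <- ncol(controlLevels)
  } else if (length(spaceLevel) == 1) {
    cm <- mean(controlLevels)
    n <- length(controlLevels)
  } else {
    stopifnot(length(controlLevels) == length(spaceLevel))
    cm <- controlLevels
    n <- 1L
  }
  data.frame(delta = spaceLevel - cm, space_level = spaceLevel,
             control_mean = cm, n_controls = as.integer(n))
}

#' Hyper/hypo/unchanged methylation proportions
#'
#' Dichotomises per-element methylation differences into hypermethylated
#' (delta > epsilon), hypomethylated (delta < -epsilon) and unchanged, and
#' returns the three proportions over the same denominator. Elements with
#' undefined levels must be excluded upstream; NA deltas are dropped here
#' with a message.
#'
#' @param deltas Numeric vector of level differences.
#' @param epsilon Dead zone around zero (default 0: any increase is hyper).
#' @return Named numeric c(p_hyper, p_hypo, p_unchanged); sums to 1 exactly
#'   (integer counts divided by a common denominator).
#' @export
hyperHypoProportions <- function(deltas, epsilon = 0) {
  if (anyNA(deltas)) {
    msg(sum(is.na(deltas)), " undefined delta(s) excluded from proportions")
    deltas <- deltas[!is.na(deltas)]
  }
  if (length(deltas) == 0)
    stop("no defined methylation differences; proportions are undefined")
  n <- length(deltas)
  hyper <- sum(deltas > epsilon)
  hypo <- sum(deltas < -epsilon)
  pH <- hyper / n
  pL <- hypo / n
  # complement of the two count ratios, so the three proportions sum to 1
  c(p_hyper = pH, p_hypo = pL, p_unchanged = 1 - (pH + pL))
}

#' Transgenerational stability of differential-methylation proportions
#'
#' Sample standard deviation (denominator n - 1) of a proportion across
#' replicate treated samples; computed per generation, it quantifies how
#' consistently a line's elements shift methylation within that generation.
#'
#' @param proportions Numeric vector of per-replicate proportions (>= 2).
#' @return The sample standard deviation.
#' @export
stabilitySD <- function(proportions) {
  if (length(proportions) < 2)
    stop("at least 2 replicate proportions are required for an SD")
  stats::sd(proportions)
}

#' Per-generation stability report
#'
#' Computes hyper/hypo/unchanged proportions for every treated sample and the
#' per-(line, generation) standard deviation of those proportions across
#' replicates.
#'
#' @param deltaMatrix Matrix of deltas, elements x treated samples.
#' @param sampleInfo data.frame with sample_id, line, generation matching the
#'   matrix columns.
#' @param epsilon Passed to [hyperHypoProportions()].
#' @return list(perSample = data.frame of per-sample proportions,
#'   perGeneration = data.frame with sd_hyper, sd_hypo per line x generation).
#' @export
stabilityReport <- function(deltaMatrix, sampleInfo, epsilon = 0) {
  stopifnot(ncol(deltaMatrix) == nrow(sampleInfo))
  props <- t(apply(deltaMatrix, 2, function(d)
    hyperHypoProportions(d, epsilon)))
  perSample <- data.frame(sample_id = sampleInfo$sample_id,
                          line = sampleInfo$line,
                          generation = sampleInfo$generation,
                          props, stringsAsFactors = FALSE)
  grp <- interaction(perSample$line, perSample$generation, drop = TRUE)
  perGen <- do.call(rbind, lapply(split(perSample, grp), function(d) {
    data.frame(line = d$line[1], generation = d$generation[1],
               n_replicates = nrow(d),
               sd_hyper = if (nrow(d) >= 2) stabilitySD(d$p_hyper) else NA,
               sd_hypo = if (nrow(d) >= 2) stabilitySD(d$p_hypo) else NA)
  }))
  perGen <- perGen[order(perGen$line, perGen$generation), , drop = FALSE]
  rownames(perGen) <- NULL
  list(perSample = perSample, perGeneration = perGen)
}
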