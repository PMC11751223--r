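#' Load a chromatin-state interval map from BED
#'
#' BED intervals whose name column labels each interval `euchromatin` or
#' `heterochromatin`. Overlapping intervals within a chromosome are
#' rejected.
#'
#' @param path BED file.
#' @return GRanges with a `state` metadata column.
#' @export
loadChromatinMap <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$name) ||
      !all(gr$name %in% c("euchromatin", "heterochromatin")))
    stop("chromatin map name column must be euchromatin/heterochromatin")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(state = gr$name)
  self <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  if (length(self) > length(gr))
    stop("chromatin intervals overlap within a chromosome")
  gr
}

#' Fraction of TIP loci in euchromatin
#'
#' Assigns each locus by its insertion point (the left breakpoint) to the
#' chromatin state at that position. Loci falling in unannotated gaps are
#' excluded from the denominator and tallied separately.
#'
#' @param loci GRanges of TIP loci.
#' @param map GRanges chromatin map from [loadChromatinMap()].
#' @return list(fraction = euchromatic fraction of annotated loci,
#'   n_euchromatin, n_heterochromatin, n_gap).
#' @export
chromatinFraction <- function(loci, map) {
  if (length(loci) == 0)
    stop("no loci supplied: euchromatic fraction undefined")
  missingChrom <- setdiff(
    unique(as.character(GenomeInfoDb::seqnames(loci))),
    unique(as.character(GenomeInfoDb::seqnames(map))))
  if (length(missingChrom))
    stop("locus chromosome(s) absent from the chromatin map: ",
         paste(missingChrom, collapse = ", "))
  pts <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(loci),
    IRanges::IRanges(GenomicRanges::start(loci), width = 1L))
  ov <- GenomicRanges::findOverlaps(pts, map, ignore.strand = TRUE,
                                    select = "first")
  state <- rep(NA_character_, length(pts))
  hit <- !is.na(ov)
  state[hit] <- map$state[ov[hit]]
  nEu <- sum(state == "euchromatin", na.rm = TRUE)
  nHet <- sum(state == "heterochromatin", na.rm = TRUE)
  nGap <- sum(is.na(state))
  if (nGap > 0) msg(nGap, " locus/loci in unannotated gaps")
  list(fraction = if (nEu + nHet > 0) nEu / (nEu + nHet) else NA_real_,
       n_euchromatin = nEu, n_heterochromatin = nHet, n_gap = nGap)
}

#' Per-bin TIP counts along chromosomes
#'
#' Divides each chromosome into fixed-width bins (half-open
#' \[k*b, (k+1)*b) in 0-based coordinates) and counts loci per bin by their
#' insertion point. All bins are emitted, including empty ones, so counts
#' across bins always sum to the number of loci.
#'
#' @param loci GRanges of TIP loci.
#' @param chromSizes Named numeric vector of chromosome lengths.
#' @param binSize Bin width in bp (default 1e6).
#' @return data.frame(chrom, bin_start, bin_end, count) with 0-based
#'   half-open bin coordinates (last bin truncated at the chromosome end).
#' @export
binCounts <- function(loci, chromSizes, binSize = 1e6) {
  stopifnot(binSize > 0, !is.null(names(chromSizes)))
  lchr <- as.character(GenomeInfoDb::seqnames(loci))
  lpos <- GenomicRanges::start(loci)
  bad <- !(lchr %in% names(chromSizes))
  if (any(bad))
    stop("locus chromosome(s) not in chromSizes: ",
         paste(unique(lchr[bad]), collapse = ", "))
  if (any(lpos > chromSizes[lchr]))
    stop("locus position beyond chromosome end")
  out <- lapply(names(chromSizes), function(ch) {
    size <- chromSizes[[ch]]
    nb <- ceiling(size / binSize)
    cnt <- tabulate(floor((lpos[lchr == ch] - 1) / binSize) + 1L,
                    nbins = nb)
    data.frame(chrom = ch,
               bin_start = (seq_len(nb) - 1) * binSize,
               bin_end = pmin(seq_len(nb) * binSize, size),
               count = cnt, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
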