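#' Load gene models from a GFF3 file
#'
#' Imports gene-type features from a GFF3 annotation and returns them as a
#' GRanges sorted by (chromosome, start). Features without a defined strand
#' are rejected (a message reports how many), since upstream/downstream
#' assignment of regulatory-region MITEs is strand-aware.
#'
#' @param path Path to a GFF3 file (1-based closed coordinates, as per the
#'   format; coordinates are carried through as-is into GRanges, which uses
#'   the same convention).
#' @param featureType GFF3 `type` values treated as genes.
#' @return GRanges with a `gene_id` metadata column.
#' @export
loadGeneModels <- function(path, featureType = "gene") {
  stopifnot(file.exists(path))
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stop("GFF3 parse error in '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  gr <- gr[as.character(gr$type) %in% featureType]
  if (length(gr) == 0) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out)$gene_id <- character(0)
    return(out)
  }
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$gene_id
  if (is.null(ids) || anyNA(ids))
    ids <- paste0("gene", seq_along(gr))
  noStrand <- as.character(GenomicRanges::strand(gr)) == "*"
  if (any(noStrand)) {
    msg(sum(noStrand), " gene record(s) without strand rejected")
    gr <- gr[!noStrand]
    ids <- ids[!noStrand]
  }
  if (anyDuplicated(ids))
    stop("gene_id values are not unique in '", path, "'")
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out)$gene_id <- as.character(ids)
  out[order(as.character(GenomeInfoDb::seqnames(out)),
            GenomicRanges::start(out), out$gene_id)]
}

#' Load MITE annotations from BED coordinates plus a sequence library
#'
#' Joins MITE locus coordinates (BED, 0-based half-open on disk; converted by
#' the importer) to element sequences (FASTA, ids matched against the BED
#' name column). Records whose name is absent from the library are retained
#' with no sequence and flagged via the `has_sequence` column.
#'
#' @param bedPath BED file of element loci; the name column carries mite ids.
#' @param libraryFasta FASTA of element sequences (optional).
#' @param tirLength Known terminal inverted repeat length in bp, recycled
#'   across elements (NA if unknown).
#' @return A [MiteSet-class].
#' @export
loadMiteAnnotations <- function(bedPath, libraryFasta = NULL,
                                tirLength = NA_integer_) {
  stopifnot(file.exists(bedPath))
  gr <- tryCatch(rtracklayer::import(bedPath, format = "bed"),
                 error = function(e)
                   stop("BED parse error in '", bedPath, "': ",
                        conditionMessage(e), call. = FALSE))
  ids <- gr$name
  if (is.null(ids)) ids <- paste0("mite", seq_along(gr))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    mite_id = as.character(ids),
    family = NA_character_,
    tir_len = as.integer(tirLength))
  seqs <- Biostrings::DNAStringSet()
  if (!is.null(libraryFasta)) {
    seqs <- Biostrings::readDNAStringSet(libraryFasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    missing <- setdiff(ids, names(seqs))
    if (length(missing))
      msg(length(missing), " MITE record(s) lack a library sequence: ",
          paste(utils::head(missing, 5), collapse = ", "))
    seqs <- seqs[intersect(ids, names(seqs))]
  }
  MiteSet(gr, seqs)
}

#' Read a MITE element library (FASTA) as a named DNAStringSet
#'
#' @param path FASTA file of element consensus/element sequences.
#' @return Named DNAStringSet.
#' @export
readMiteLibrary <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  if (length(s) == 0) stop("MITE library '", path, "' is empty")
  names(s) <- sub("\\s.*$", "", names(s))
  s
}

#' Assign MITEs to gene regulatory regions
#'
#' Links every MITE that overlaps the window extending `window` bp on either
#' side of a gene body to that gene. A MITE may link to several genes. The
#' relation is computed relative to gene strand by default (`upstream` = the
#' gene's 5' side), matching how regulatory regions are described; genomic
#' left/right is available with `strandAware = FALSE`. Any overlap with the
#' window counts (an element partially inside the window is in); set
#' `requireContained = TRUE` to demand full containment.
#'
#' @param mites [MiteSet-class] or GRanges with `mite_id`.
#' @param genes GRanges with `gene_id` (from [loadGeneModels()]).
#' @param window Regulatory window size in bp on each side (default 2000, the
#'   conventional 2-kb promoter/terminator window).
#' @param strandAware Compute upstream/downstream relative to gene strand.
#' @param requireContained Require the element fully inside the window.
#' @return data.frame with columns mite_id, gene_id, relation
#'   (upstream/downstream/overlapping), distance (bp gap to the gene body; 0
#'   when overlapping).
#' @export
assignRegulatoryContext <- function(mites, genes, window = 2000,
                                    strandAware = TRUE,
                                    requireContained = FALSE) {
  stopifnot(window > 0)
  mr <- if (is(mites, "MiteSet")) miteRanges(mites) else mites
  if (length(mr) == 0 || length(genes) == 0)
    return(data.frame(mite_id = character(), gene_id = character(),
                      relation = character(), distance = integer()))
  win <- GenomicRanges::resize(genes,
                               GenomicRanges::width(genes) + 2 * window,
                               fix = "center")
  ov <- GenomicRanges::findOverlaps(
    mr, win,
    type = if (requireContained) "within" else "any",
    ignore.strand = TRUE)
  if (length(ov) == 0)
    return(data.frame(mite_id = character(), gene_id = character(),
                      relation = character(), distance = integer()))
  m <- mr[S4Vectors::queryHits(ov)]
  g <- genes[S4Vectors::subjectHits(ov)]
  ms <- GenomicRanges::start(m); me <- GenomicRanges::end(m)
  gs <- GenomicRanges::start(g); ge <- GenomicRanges::end(g)
  overlapping <- ms <= ge & me >= gs
  leftOf <- me < gs        # MITE entirely left of the gene body
  dist <- integer(length(ov))
  dist[leftOf] <- gs[leftOf] - me[leftOf] - 1L
  rightOf <- ms > ge
  dist[rightOf] <- ms[rightOf] - ge[rightOf] - 1L
  rel <- character(length(ov))
  rel[overlapping] <- "overlapping"
  minus <- strandAware & as.character(GenomicRanges::strand(g)) == "-"
  rel[leftOf & !minus] <- "upstream"
  rel[leftOf & minus] <- "downstream"
  rel[rightOf & !minus] <- "downstream"
  rel[rightOf & minus] <- "upstream"
  out <- data.frame(
    mite_id = S4Vectors::mcols(m)$mite_id,
    gene_id = S4Vectors::mcols(g)$gene_id,
    relation = rel,
    distance = dist,
    stringsAsFactors = FALSE)
  out <- out[order(out$mite_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes neighbouring a TIP insertion point
#'
#' For an insertion locus, returns the gene overlapping the insertion point
#' (if any) plus up to `kEachSide` nearest non-overlapping genes on each
#' genomic side, the convention used when characterising insertion-site
#' context (left/right of the breakpoint, not gene-strand-aware). Distance
#' ties are broken by (start, gene_id).
#'
#' @param chrom Chromosome name.
#' @param pos Insertion point (1-based bp).
#' @param genes GRanges with `gene_id`.
#' @param kEachSide Number of flanking genes per side (default 2).
#' @return data.frame(gene_id, side = left/right/overlapping, distance),
#'   ordered overlapping first, then by distance.
#' @export
neighborGenes <- function(chrom, pos, genes, kEachSide = 2) {
  stopifnot(kEachSide >= 1)
  on <- genes[as.character(GenomeInfoDb::seqnames(genes)) == chrom]
  if (length(on) == 0) {
    msg("chromosome '", chrom, "' absent from gene set")
    return(data.frame(gene_id = character(), side = character(),
                      distance = integer()))
  }
  gs <- GenomicRanges::start(on); ge <- GenomicRanges::end(on)
  id <- S4Vectors::mcols(on)$gene_id
  hit <- gs <= pos & ge >= pos
  left <- which(ge < pos)
  right <- which(gs > pos)
  pick <- function(idx, d) {
    o <- order(d, gs[idx], id[idx])
    idx[o][seq_len(min(kEachSide, length(idx)))]
  }
  li <- pick(left, pos - ge[left])
  ri <- pick(right, gs[right] - pos)
  out <- rbind(
    if (any(hit)) data.frame(gene_id = id[hit], side = "overlapping",
                             distance = 0L),
    if (length(li)) data.frame(gene_id = id[li], side = "left",
                               distance = pos - ge[li]),
    if (length(ri)) data.frame(gene_id = id[ri], side = "right",
                               distance = gs[ri] - pos))
  if (is.null(out))
    return(data.frame(gene_id = character(), side = character(),
                      distance = integer()))
  out <- out[order(out$distance, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Neighbour genes for a set of TIP loci
#'
#' Applies [neighborGenes()] to each locus and returns the combined table
#' (at most 2 x kEachSide + 1 genes per locus).
#'
#' @param loci GRanges of TIP loci with a `locus_id` metadata column.
#' @param genes GRanges with `gene_id`.
#' @param kEachSide Flanking genes per side.
#' @return data.frame(locus_id, gene_id, side, distance).
#' @export
neighborGeneSets <- function(loci, genes, kEachSide = 2) {
  if (length(loci) == 0)
    return(data.frame(locus_id = character(), gene_id = character(),
                      side = character(), distance = integer()))
  res <- lapply(seq_along(loci), function(i) {
    nb <- neighborGenes(as.character(GenomeInfoDb::seqnames(loci[i])),
                        GenomicRanges::start(loci[i]), genes, kEachSide)
    if (nrow(nb)) cbind(locus_id = loci$locus_id[i], nb) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(locus_id = character(), gene_id = character(),
                      side = character(), distance = integer())
  rownames(out) <- NULL
  out
}
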