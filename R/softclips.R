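refWidthFromCigar <- function(cigar) {
  as.integer(sum(BiocGenerics::width(
    GenomicAlignments::cigarRangesAlongReferenceSpace(cigar))))
}

#' Read primary alignments from a SAM/BAM file
#'
#' Loads primary, non-duplicate, non-supplementary mapped alignments. BAM is
#' read through Rsamtools; plain-text SAM (a tab-separated table after its
#' `@` header) is read directly, with CIGAR/sequence-length consistency
#' checked on every record. Both routes return identical tables.
#'
#' @param path SAM or BAM file. A SAM file must carry a header.
#' @return data.frame(qname, flag, rname, pos, mapq, cigar, seq, refWidth)
#'   where pos is the 1-based leftmost aligned position and refWidth the
#'   reference footprint implied by the CIGAR.
#' @export
readSamAlignments <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    flg <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE)
    p <- Rsamtools::ScanBamParam(
      flag = flg,
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"))
    res <- Rsamtools::scanBam(path, param = p)[[1]]
    return(data.frame(
      qname = res$qname, flag = res$flag,
      rname = as.character(res$rname), pos = res$pos, mapq = res$mapq,
      cigar = res$cigar, seq = as.character(res$seq),
      refWidth = refWidthFromCigar(res$cigar), stringsAsFactors = FALSE))
  }
  nProbe <- 1000L
  repeat {
    head <- readLines(path, n = nProbe)
    if (length(head) == 0 || !startsWith(head[1], "@"))
      stop("SAM file '", path, "' is missing a header")
    idx <- match(FALSE, startsWith(head, "@"))
    if (!is.na(idx)) { nHeader <- idx - 1L; break }
    if (length(head) < nProbe) { nHeader <- length(head); break }
    nProbe <- nProbe * 2L
  }
  empty <- data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(),
                      mapq = integer(), cigar = character(),
                      seq = character(), refWidth = integer(),
                      stringsAsFactors = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = FALSE, fill = TRUE,
                          skip = nHeader, select = c(1:6, 10),
                          colClasses = list(character = c(1, 3, 6, 10),
                                            integer = c(2, 4, 5)),
                          showProgress = FALSE)
  if (nrow(dt) == 0) return(empty)
  if (ncol(dt) < 7 || anyNA(dt[[2]]) || anyNA(dt[[4]]))
    stop("malformed SAM record(s) in '", path, "'")
  # primary, mapped, non-duplicate, non-supplementary records only
  keep <- bitwAnd(dt[[2]], 0xD04L) == 0L
  dt <- dt[keep, ]
  if (nrow(dt) == 0) return(empty)
  qw <- as.integer(sum(BiocGenerics::width(
    GenomicAlignments::cigarRangesAlongQuerySpace(dt[[6]]))))
  badLen <- which(dt[[6]] != "*" & qw != nchar(dt[[7]]))
  if (length(badLen))
    stop("CIGAR and sequence length disagree in '", path,
         "' (e.g. read ", dt[[1]][badLen[1]], ")")
  data.frame(qname = dt[[1]], flag = dt[[2]], rname = dt[[3]],
             pos = dt[[4]], mapq = dt[[5]], cigar = dt[[6]],
             seq = dt[[7]], refWidth = refWidthFromCigar(dt[[6]]),
             stringsAsFactors = FALSE)
}

#' Extract soft-clip evidence from alignments
#'
#' One evidence record per terminal soft-clipped segment (CIGAR `S`) of
#' length at least `minClip` on a primary alignment with mapping quality at
#' least `minMapq`. A left clip's breakpoint is the first aligned reference
#' base (the alignment start); a right clip's breakpoint is the last aligned
#' reference base (the alignment end). At a transposon insertion junction the
#' clipped bases derive from the inserted element, so the clipped sequence is
#' retained for library matching.
#'
#' @param aln Alignment table from [readSamAlignments()], or a SAM/BAM path.
#' @param minClip Minimum clipped-segment length in bp (default 10, the
#'   conventional floor below which a clip cannot be aligned confidently).
#' @param minMapq Minimum mapping quality (default 20).
#' @return data.frame(chrom, breakpoint, side = left_clip/right_clip,
#'   clipped_seq, read_id).
#' @export
extractSoftClips <- function(aln, minClip = 10, minMapq = 20) {
  if (is.character(aln)) aln <- readSamAlignments(aln)
  empty <- data.frame(chrom = character(), breakpoint = integer(),
                      side = character(), clipped_seq = character(),
                      read_id = character(), stringsAsFactors = FALSE)
  if (nrow(aln) == 0) return(empty)
  aln <- aln[!is.na(aln$mapq) & aln$mapq >= minMapq & !is.na(aln$cigar), ,
             drop = FALSE]
  if (nrow(aln) == 0) return(empty)
  leftLen <- suppressWarnings(
    as.integer(sub("^([0-9]+)S.*$", "\\1",
                   ifelse(grepl("^[0-9]+S", aln$cigar), aln$cigar, "0S"))))
  rightLen <- suppressWarnings(
    as.integer(sub("^.*?([0-9]+)S$", "\\1",
                   ifelse(grepl("[0-9]+S$", aln$cigar), aln$cigar, "0S"))))
  out <- list()
  li <- which(leftLen >= minClip)
  if (length(li))
    out$left <- data.frame(
      chrom = aln$rname[li],
      breakpoint = aln$pos[li],
      side = "left_clip",
      clipped_seq = substr(aln$seq[li], 1L, leftLen[li]),
      read_id = aln$qname[li], stringsAsFactors = FALSE)
  ri <- which(rightLen >= minClip)
  if (length(ri)) {
    readLen <- nchar(aln$seq[ri])
    out$right <- data.frame(
      chrom = aln$rname[ri],
      breakpoint = aln$pos[ri] + aln$refWidth[ri] - 1L,
      side = "right_clip",
      clipped_seq = substr(aln$seq[ri], readLen - rightLen[ri] + 1L,
                           readLen),
      read_id = aln$qname[ri], stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$breakpoint, res$side, res$read_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Cluster soft-clip breakpoints
#'
#' Single-linkage clustering of evidence breakpoints per (chromosome, clip
#' side): consecutive breakpoints at most `clusterTol` bp apart join the same
#' cluster. The consensus position is the modal breakpoint (smallest on
#' ties).
#'
#' @param evidence data.frame from [extractSoftClips()].
#' @param clusterTol Maximum gap between neighbouring member breakpoints
#'   (default 3 bp).
#' @return data.frame(chrom, position, side, support) with the member clipped
#'   sequences as a list column `clipped_seqs`.
#' @export
clusterBreakpoints <- function(evidence, clusterTol = 3) {
  empty <- data.frame(chrom = character(), position = integer(),
                      side = character(), support = integer(),
                      stringsAsFactors = FALSE)
  empty$clipped_seqs <- list()
  if (is.null(evidence) || nrow(evidence) == 0) return(empty)
  ev <- evidence[order(evidence$chrom, evidence$side, evidence$breakpoint), ,
                 drop = FALSE]
  key <- paste(ev$chrom, ev$side)
  newGrp <- c(TRUE, key[-1] != key[-nrow(ev)] |
                diff(ev$breakpoint) > clusterTol)
  grp <- cumsum(newGrp)
  parts <- split(seq_len(nrow(ev)), grp)
  rows <- lapply(parts, function(idx) {
    bp <- ev$breakpoint[idx]
    tab <- table(bp)
    consensus <- as.integer(names(tab)[which.max(tab)])  # modal; ties -> smallest
    data.frame(chrom = ev$chrom[idx[1]], position = consensus,
               side = ev$side[idx[1]], support = length(idx),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$clipped_seqs <- lapply(parts, function(idx) ev$clipped_seq[idx])
  out <- out[order(out$chrom, out$position, out$side), , drop = FALSE]
  rownames(out) <- NULL
  out
}
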