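asGenome <- function(ref) {
  if (is.character(ref) && length(ref) == 1 && file.exists(ref)) {
    g <- Biostrings::readDNAStringSet(ref)
    names(g) <- sub("\\s.*$", "", names(g))
    g
  } else if (is(ref, "DNAStringSet")) ref
  else stop("reference must be a FASTA path or a DNAStringSet")
}

asLibrary <- function(library) {
  if (is(library, "MiteSet")) library <- miteSequences(library)
  if (is.character(library) && length(library) == 1 && file.exists(library))
    library <- readMiteLibrary(library)
  if (!is(library, "DNAStringSet") || length(library) == 0 ||
      is.null(names(library)))
    stop("MITE library must be a non-empty named DNAStringSet, MiteSet or ",
         "FASTA path")
  library
}

# Precompute the four terminus orientations of every library element:
# 5prime/forward = element start, 3prime/forward = element end,
# 5prime/reverse = start of the reverse complement, 3prime/reverse = its end.
# Terminus labels refer to the inserted (oriented) copy.
libraryTermini <- function(library) {
  fwd <- as.character(library)
  rc <- revComp(fwd)
  list(ids = names(library), fwd = unname(fwd), rc = unname(rc))
}

# returns "mite_id\tterminus\torientation" keys for every library terminus
# the clip matches (NULL if none)
matchOneClip <- function(clip, term, minMatch, maxMismatchPer10) {
  k <- nchar(clip)
  if (k < minMatch) return(NULL)
  allowed <- floor(k / 10) * maxMismatchPer10
  hits <- character(0)
  for (i in seq_along(term$ids)) {
    for (orient in c("forward", "reverse")) {
      s <- if (orient == "forward") term$fwd[i] else term$rc[i]
      n <- nchar(s)
      if (n < k) next
      if (strMismatches(clip, substr(s, 1L, k)) <= allowed)
        hits <- c(hits, paste(term$ids[i], "5prime", orient, sep = "\t"))
      if (strMismatches(clip, substr(s, n - k + 1L, n)) <= allowed)
        hits <- c(hits, paste(term$ids[i], "3prime", orient, sep = "\t"))
    }
  }
  if (length(hits)) hits else NULL
}

#' Match a breakpoint cluster's clipped sequences to a MITE library
#'
#' Compares every clipped sequence of a cluster, in both orientations,
#' against the 5' and 3' termini of each library element by ungapped
#' comparison (at most `maxMismatchPer10` mismatches per started 10 bp of
#' clip; clips shorter than `minMatch` are ignored). The cluster-level call
#' is the (element, terminus, orientation) supported by the plurality of
#' clips; ties prefer forward orientation, then the 5' terminus, then the
#' lexicographically first element id. Because a MITE's terminal inverted
#' repeats make its 5' start and reverse-complemented 3' end identical,
#' clips shorter than the TIR vote for both orientations and the longer
#' clips decide.
#'
#' @param clippedSeqs Character vector of clipped sequences (one cluster).
#' @param library Named DNAStringSet / MiteSet / FASTA path.
#' @param minMatch Minimum clip length used for matching (default 10).
#' @param maxMismatchPer10 Allowed mismatches per 10 bp of clip (default 1).
#' @return list(mite_id, terminus, orientation, votes, n_matching) or NULL if
#'   nothing matches.
#' @export
matchMiteLibrary <- function(clippedSeqs, library, minMatch = 10,
                             maxMismatchPer10 = 1) {
  library <- asLibrary(library)
  term <- libraryTermini(library)
  all <- lapply(clippedSeqs, matchOneClip, term = term, minMatch = minMatch,
                maxMismatchPer10 = maxMismatchPer10)
  nMatching <- sum(!vapply(all, is.null, TRUE))
  keys <- unlist(all, use.names = FALSE)
  if (length(keys) == 0) return(NULL)
  tab <- table(keys)
  parts <- do.call(rbind, strsplit(names(tab), "\t", fixed = TRUE))
  o <- order(-as.integer(tab), parts[, 3] != "forward",
             parts[, 2] != "5prime", parts[, 1])[1]
  list(mite_id = parts[o, 1], terminus = parts[o, 2],
       orientation = parts[o, 3], votes = as.integer(tab[o]),
       n_matching = nMatching)
}

#' Detect a target site duplication between paired breakpoint clusters
#'
#' At a genuine insertion with a duplicated target site spanning reference
#' interval \[t, t+L-1\], reads crossing the insertion's 5' junction are
#' right-clipped with alignment end t+L-1 and reads crossing its 3' junction
#' are left-clipped with alignment start t: the left-clip cluster sits
#' upstream of the right-clip cluster and the TSD is the reference interval
#' between them (inclusive).
#'
#' @param leftCluster,rightCluster Single rows of [clusterBreakpoints()]
#'   output with sides left_clip and right_clip on the same chromosome.
#' @param ref Genome (DNAStringSet or FASTA path).
#' @param tsdRange Allowed TSD length range in bp (default 2-10, covering
#'   the short direct repeats typical of MITE superfamilies).
#' @return The TSD sequence, or NULL if the cluster offset is outside
#'   `tsdRange`.
#' @export
detectTsd <- function(leftCluster, rightCluster, ref, tsdRange = c(2, 10)) {
  if (leftCluster$side != "left_clip" || rightCluster$side != "right_clip")
    stop("detectTsd expects a left_clip and a right_clip cluster")
  if (leftCluster$chrom != rightCluster$chrom)
    stop("breakpoint clusters lie on different chromosomes (",
         leftCluster$chrom, " vs ", rightCluster$chrom, ")")
  ref <- asGenome(ref)
  L <- rightCluster$position - leftCluster$position + 1L
  if (L < tsdRange[1] || L > tsdRange[2]) return(NULL)
  as.character(Biostrings::subseq(ref[[leftCluster$chrom]],
                                  leftCluster$position,
                                  rightCluster$position))
}

# depth = number of primary alignments whose reference footprint overlaps
# [start, end] on chrom (clipped and non-clipped reads alike)
locusDepth <- function(aln, chrom, start, end) {
  sum(aln$rname == chrom & aln$pos <= end &
        aln$pos + aln$refWidth - 1L >= start)
}

#' Call MITE insertion polymorphisms from soft-clipped reads
#'
#' Full TIP-calling pipeline for one sample: extract terminal soft clips
#' (>= `minClip` bp, the 10-bp floor below which a clipped fragment cannot
#' be assigned), cluster breakpoints, pair left-clip with right-clip
#' clusters whose offset matches a target-site-duplication length, demand
#' total read depth at the junction interval of at least `minDepth` (the 5x
#' rule), and require the two junction clusters to match opposite termini of
#' the same library element in a consistent orientation. Loci are returned
#' sorted by (chromosome, position).
#'
#' @param sam SAM/BAM path or an alignment table from [readSamAlignments()].
#' @param ref Genome FASTA path or DNAStringSet.
#' @param library MITE element library (named DNAStringSet, MiteSet or FASTA
#'   path).
#' @param minClip Minimum soft-clip length (default 10 bp).
#' @param minMapq Minimum mapping quality (default 20).
#' @param minDepth Minimum read depth over the TSD interval (default 5).
#' @param clusterTol Breakpoint clustering tolerance (default 3 bp).
#' @param tsdRange TSD length range (default 2-10 bp).
#' @param minMatch,maxMismatchPer10 Passed to [matchMiteLibrary()].
#' @param sample Optional sample id recorded on the calls.
#' @return GRanges of TIP loci: each range is the TSD interval, with
#'   metadata locus_id, mite_id, orientation, tsd_seq, support_left,
#'   support_right, depth, sample.
#' @export
callTips <- function(sam, ref, library, minClip = 10, minMapq = 20,
                     minDepth = 5, clusterTol = 3, tsdRange = c(2, 10),
                     minMatch = 10, maxMismatchPer10 = 1,
                     sample = NA_character_) {
  ref <- asGenome(ref)
  library <- asLibrary(library)
  aln <- if (is.character(sam)) readSamAlignments(sam) else sam
  emptyCalls <- function() {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      locus_id = character(), mite_id = character(),
      orientation = character(), tsd_seq = character(),
      support_left = integer(), support_right = integer(),
      depth = integer(), sample = character())
    gr
  }
  if (nrow(aln) == 0) return(emptyCalls())
  badChrom <- setdiff(unique(aln$rname), names(ref))
  if (length(badChrom))
    stop("alignment chromosome(s) absent from the reference: ",
         paste(badChrom, collapse = ", "))
  ev <- extractSoftClips(aln, minClip = minClip, minMapq = minMapq)
  cl <- clusterBreakpoints(ev, clusterTol = clusterTol)
  lefts <- which(cl$side == "left_clip")
  rights <- which(cl$side == "right_clip")
  rows <- list()
  for (li in lefts) {
    for (ri in rights) {
      if (cl$chrom[ri] != cl$chrom[li]) next
      L <- cl$position[ri] - cl$position[li] + 1L
      if (L < tsdRange[1] || L > tsdRange[2]) next
      start <- cl$position[li]; end <- cl$position[ri]
      depth <- locusDepth(aln, cl$chrom[li], start, end)
      if (depth < minDepth) next
      m5 <- matchMiteLibrary(cl$clipped_seqs[[ri]], library,
                             minMatch = minMatch,
                             maxMismatchPer10 = maxMismatchPer10)
      m3 <- matchMiteLibrary(cl$clipped_seqs[[li]], library,
                             minMatch = minMatch,
                             maxMismatchPer10 = maxMismatchPer10)
      if (is.null(m5) || is.null(m3)) next
      if (m5$mite_id != m3$mite_id ||
          m5$orientation != m3$orientation) next
      if (m5$terminus != "5prime" || m3$terminus != "3prime") next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cl$chrom[li], start = start, end = end,
        mite_id = m5$mite_id, orientation = m5$orientation,
        tsd_seq = as.character(Biostrings::subseq(ref[[cl$chrom[li]]],
                                                  start, end)),
        support_left = cl$support[li], support_right = cl$support[ri],
        depth = depth, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(emptyCalls())
  df <- do.call(rbind, rows)
  # one call per junction cluster: on competing pairings keep the best
  # supported, then the shortest TSD
  df <- df[order(-(df$support_left + df$support_right),
                 df$end - df$start), , drop = FALSE]
  df <- df[!duplicated(paste(df$chrom, df$start)) &
             !duplicated(paste(df$chrom, df$end)), , drop = FALSE]
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end),
    locus_id = paste0(df$chrom, ":", df$start, "-", df$end),
    mite_id = df$mite_id, orientation = df$orientation,
    tsd_seq = df$tsd_seq, support_left = df$support_left,
    support_right = df$support_right, depth = df$depth,
    sample = sample)
  GenomeInfoDb::seqlevels(gr) <- names(ref)
  sort(gr)
}

#' Differential TIP loci between two call sets
#'
#' Loci present in one call set and absent from the other, where "the same
#' locus" tolerates a small breakpoint displacement (`locusTol`). Mirrors
#' the initial comparison of each treated sample against a control
#' reference, labelled by direction.
#'
#' @param sampleCalls,referenceCalls GRanges from [callTips()].
#' @param locusTol Maximum breakpoint distance for two calls to be the same
#'   locus (default 5 bp).
#' @return GRanges of differential loci with a `direction` column
#'   (`sample_only` / `reference_only`).
#' @export
diffTips <- function(sampleCalls, referenceCalls, locusTol = 5) {
  near <- function(a, b) {
    if (length(a) == 0) return(logical(0))
    if (length(b) == 0) return(rep(FALSE, length(a)))
    sameChrom <- outer(as.character(GenomeInfoDb::seqnames(a)),
                       as.character(GenomeInfoDb::seqnames(b)), "==")
    close <- abs(outer(GenomicRanges::start(a),
                       GenomicRanges::start(b), "-")) <= locusTol
    rowSums(sameChrom & close) > 0
  }
  so <- sampleCalls[!near(sampleCalls, referenceCalls)]
  ro <- referenceCalls[!near(referenceCalls, sampleCalls)]
  so$direction <- rep("sample_only", length(so))
  ro$direction <- rep("reference_only", length(ro))
  suppressWarnings(c(so, ro))
}

#' Deduplicate TIP loci across samples
#'
#' Collapses calls from many samples into a unique locus list, merging calls
#' whose breakpoints lie within `locusTol` of each other (first-seen
#' coordinates win; calls sorted first so the result is deterministic).
#'
#' @param calls GRanges (possibly concatenated across samples).
#' @param locusTol Merge tolerance in bp.
#' @return GRanges of unique loci.
#' @export
dedupeLoci <- function(calls, locusTol = 5) {
  if (length(calls) == 0) return(calls)
  calls <- sort(calls)
  keep <- rep(TRUE, length(calls))
  lastChrom <- ""; lastStart <- -Inf
  for (i in seq_along(calls)) {
    ch <- as.character(GenomeInfoDb::seqnames(calls[i]))
    st <- GenomicRanges::start(calls[i])
    if (ch == lastChrom && abs(st - lastStart) <= locusTol) {
      keep[i] <- FALSE
    } else {
      lastChrom <- ch; lastStart <- st
    }
  }
  calls[keep]
}

#' Reconfirm TIP loci across all samples
#'
#' Genotypes a list of candidate loci in every sample: a locus is `present`
#' when at least `minSupport` soft-clip reads near either junction match the
#' called element, `no_data` when the sample has no read coverage at the
#' locus at all, and `absent` otherwise (covered but unsupported).
#'
#' @param loci GRanges of candidate loci (with locus_id, mite_id).
#' @param samFiles Named character vector of SAM/BAM paths (names = sample
#'   ids).
#' @param ref Genome.
#' @param library MITE library.
#' @param minSupport Minimum matching clip reads for presence (default 1).
#' @param locusTol Breakpoint match tolerance (default 5 bp).
#' @param minClip,minMapq,minMatch,maxMismatchPer10 Evidence thresholds as in
#'   [callTips()].
#' @param sampleInfo Optional data.frame of sample metadata (sample_id plus
#'   e.g. group), carried into the result.
#' @return A [TipPresenceMatrix-class].
#' @export
reconfirmLoci <- function(loci, samFiles, ref, library, minSupport = 1,
                          locusTol = 5, minClip = 10, minMapq = 20,
                          minMatch = 10, maxMismatchPer10 = 1,
                          sampleInfo = NULL) {
  stopifnot(!is.null(names(samFiles)))
  missingSam <- names(samFiles)[!file.exists(unlist(samFiles))]
  if (length(missingSam))
    stop("missing alignment file(s) for sample(s): ",
         paste(missingSam, collapse = ", "))
  ref <- asGenome(ref)
  library <- asLibrary(library)
  term <- libraryTermini(library)
  pres <- matrix("absent", nrow = length(loci), ncol = length(samFiles),
                 dimnames = list(loci$locus_id, names(samFiles)))
  lchr <- as.character(GenomeInfoDb::seqnames(loci))
  lst <- GenomicRanges::start(loci); len <- GenomicRanges::end(loci)
  for (s in seq_along(samFiles)) {
    aln <- readSamAlignments(samFiles[[s]])
    ev <- extractSoftClips(aln, minClip = minClip, minMapq = minMapq)
    for (i in seq_along(loci)) {
      depth <- locusDepth(aln, lchr[i], lst[i], len[i])
      if (depth == 0) { pres[i, s] <- "no_data"; next }
      nearJ <- ev$chrom == lchr[i] &
        ((ev$side == "left_clip" & abs(ev$breakpoint - lst[i]) <= locusTol) |
         (ev$side == "right_clip" & abs(ev$breakpoint - len[i]) <= locusTol))
      if (!any(nearJ)) next
      clips <- ev$clipped_seq[nearJ]
      elem <- loci$mite_id[i]
      nSupp <- 0L
      for (cp in clips) {
        hits <- matchOneClip(cp, term, minMatch, maxMismatchPer10)
        if (!is.null(hits) && any(startsWith(hits, paste0(elem, "\t"))))
          nSupp <- nSupp + 1L
      }
      if (nSupp >= minSupport) pres[i, s] <- "present"
    }
  }
  samples <- if (is.null(sampleInfo)) {
    data.frame(sample_id = names(samFiles), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(names(samFiles) %in% sampleInfo$sample_id))
    sampleInfo[match(names(samFiles), sampleInfo$sample_id), , drop = FALSE]
  }
  new("TipPresenceMatrix", loci = loci, samples = samples, presence = pres)
}

#' Treatment-induced TIP loci
#'
#' Loci present in at least one treated ("space") sample and absent from
#' every control sample. A control with `no_data` at a locus disqualifies it
#' (absence cannot be established there); disqualified loci are reported via
#' a message.
#'
#' @param tpm A [TipPresenceMatrix-class].
#' @param groups Named character vector sample_id -> "space"/"control", or
#'   NULL to use the `group` column of the matrix's sample metadata.
#' @return GRanges subset of the matrix loci that are treatment-induced.
#' @export
spaceInduced <- function(tpm, groups = NULL) {
  p <- presence(tpm)
  samples <- tipSamples(tpm)
  if (is.null(groups)) {
    if (is.null(samples$group))
      stop("no group labels: supply `groups` or sample metadata with a ",
           "`group` column")
    groups <- stats::setNames(samples$group, samples$sample_id)
  }
  unlabeled <- setdiff(colnames(p), names(groups))
  if (length(unlabeled))
    stop("sample(s) without a group label: ",
         paste(unlabeled, collapse = ", "))
  g <- groups[colnames(p)]
  if (ncol(p) == 0 || nrow(p) == 0) return(tipLoci(tpm)[integer(0)])
  spaceCols <- g == "space"; ctrlCols <- g == "control"
  anySpace <- apply(p[, spaceCols, drop = FALSE] == "present", 1, any)
  allCtrlAbsent <- apply(p[, ctrlCols, drop = FALSE] == "absent", 1, all)
  ctrlNoData <- apply(p[, ctrlCols, drop = FALSE] == "no_data", 1, any)
  if (any(anySpace & ctrlNoData))
    msg(sum(anySpace & ctrlNoData),
        " locus/loci disqualified: no control coverage")
  tipLoci(tpm)[anySpace & allCtrlAbsent]
}

#' Write TIP calls as BED6+
#'
#' BED-style TSV (0-based half-open starts): chrom, start, end, locus_id,
#' support (left+right), strand (+ for a forward-orientation insertion, -
#' for reverse), then tsd_seq and mite_id as extra columns.
#'
#' @param calls GRanges from [callTips()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeTipBed <- function(calls, path) {
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(calls)),
    start = GenomicRanges::start(calls) - 1L,
    end = GenomicRanges::end(calls),
    locus_id = calls$locus_id,
    support = calls$support_left + calls$support_right,
    strand = ifelse(calls$orientation == "forward", "+", "-"),
    tsd_seq = calls$tsd_seq,
    mite_id = calls$mite_id, stringsAsFactors = FALSE)
  con <- file(path, "wt")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
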