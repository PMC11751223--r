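# Shared fixture builders: everything is generated in code at test time.

randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# element with perfect terminal inverted repeats
makeElement <- function(len, tirLen) {
  tir <- randomSeq(tirLen)
  paste0(tir, randomSeq(len - 2L * tirLen), revComp(tir))
}

samHeaderLines <- function(chroms, lens) {
  c("@HD\tVN:1.6\tSO:unsorted",
    paste0("@SQ\tSN:", chroms, "\tLN:", lens))
}

samLine <- function(qname, flag, rname, pos, mapq, cigar, seq) {
  paste(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, seq,
        strrep("I", nchar(seq)), sep = "\t")
}

writeSam <- function(lines, chroms, lens, path = tempfile(fileext = ".sam")) {
  writeLines(c(samHeaderLines(chroms, lens), lines), path)
  path
}

# a read fully mapped to ref[start, start+R-1]
bgRead <- function(ref, start, R = 100, qname = paste0("bg", start)) {
  samLine(qname, 0, "chr1", start, 60, paste0(R, "M"),
          substr(ref, start, start + R - 1))
}

# junction-spanning read for an insertion whose TSD occupies
# ref[site, site+tsdLen-1]; side "five" = right-clipped (mapped part ends on
# the last TSD base), side "three" = left-clipped (mapped part starts on the
# first TSD base); m = mapped length.
junctionRead <- function(ref, ins, site, tsdLen, side, m, R = 100,
                         qname = paste0("j", side, m)) {
  clip <- R - m
  if (side == "five") {
    pos <- site + tsdLen - m
    seq <- paste0(substr(ref, pos, site + tsdLen - 1),
                  substr(ins, 1, clip))
    samLine(qname, 0, "chr1", pos, 60, paste0(m, "M", clip, "S"), seq)
  } else {
    seq <- paste0(substr(ins, nchar(ins) - clip + 1, nchar(ins)),
                  substr(ref, site, site + m - 1))
    samLine(qname, 0, "chr1", site, 60, paste0(clip, "S", m, "M"), seq)
  }
}

# complete single-insertion fixture: reference, element library, and a SAM
# with the requested junction and background reads
tipFixture <- function(seed = 1, refLen = 4000, elemLen = 150, tirLen = 12,
                       site = 2000, tsdLen = 3, orientation = "forward",
                       m5 = c(60, 70, 80), m3 = c(60, 70, 80),
                       nBg = 0, bgStarts = NULL) {
  set.seed(seed)
  ref <- randomSeq(refLen)
  elem <- makeElement(elemLen, tirLen)
  ins <- if (orientation == "forward") elem else revComp(elem)
  lines <- c(
    vapply(m5, function(m)
      junctionRead(ref, ins, site, tsdLen, "five", m,
                   qname = paste0("j5_", m)), ""),
    vapply(m3, function(m)
      junctionRead(ref, ins, site, tsdLen, "three", m,
                   qname = paste0("j3_", m)), ""))
  if (is.null(bgStarts) && nBg > 0)
    bgStarts <- seq(100, 100 + (nBg - 1) * 120, length.out = nBg)
  if (length(bgStarts))
    lines <- c(lines, vapply(seq_along(bgStarts), function(i)
      bgRead(ref, bgStarts[i], qname = paste0("bg", i)), ""))
  lib <- Biostrings::DNAStringSet(setNames(elem, "M1"))
  genome <- Biostrings::DNAStringSet(setNames(ref, "chr1"))
  list(ref = ref, refSet = genome, elem = elem, lib = lib, site = site,
       tsdLen = tsdLen, tsd = substr(ref, site, site + tsdLen - 1),
       sam = writeSam(lines, "chr1", refLen))
}

# brute-force all-pairs regulatory-context oracle (O(n*m) interval scan)
bruteForceLinks <- function(mites, genes, window = 2000,
                            strandAware = TRUE) {
  out <- list()
  for (i in seq_along(mites)) {
    for (j in seq_along(genes)) {
      if (as.character(GenomeInfoDb::seqnames(mites[i])) !=
          as.character(GenomeInfoDb::seqnames(genes[j]))) next
      ms <- GenomicRanges::start(mites[i]); me <- GenomicRanges::end(mites[i])
      gs <- GenomicRanges::start(genes[j]); ge <- GenomicRanges::end(genes[j])
      if (me < gs - window || ms > ge + window) next
      minus <- strandAware &&
        as.character(GenomicRanges::strand(genes[j])) == "-"
      if (ms <= ge && me >= gs) {
        rel <- "overlapping"; d <- 0L
      } else if (me < gs) {
        rel <- if (minus) "downstream" else "upstream"
        d <- gs - me - 1L
      } else {
        rel <- if (minus) "upstream" else "downstream"
        d <- ms - ge - 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        mite_id = mites$mite_id[i], gene_id = genes$gene_id[j],
        relation = rel, distance = d, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(mite_id = character(), gene_id = character(),
                      relation = character(), distance = integer()))
  res <- res[order(res$mite_id, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

randomAnnotation <- function(nGenes = 25, nMites = 50, chroms = c("chrA", "chrB"),
                             chromLen = 100000) {
  genes <- GenomicRanges::GRanges(
    sample(chroms, nGenes, replace = TRUE),
    IRanges::IRanges(start = sample(chromLen - 3000, nGenes),
                     width = sample(500:2000, nGenes, replace = TRUE)),
    strand = sample(c("+", "-"), nGenes, replace = TRUE),
    gene_id = sprintf("g%03d", seq_len(nGenes)))
  mites <- GenomicRanges::GRanges(
    sample(chroms, nMites, replace = TRUE),
    IRanges::IRanges(start = sample(chromLen - 500, nMites),
                     width = sample(100:400, nMites, replace = TRUE)),
    mite_id = sprintf("m%03d", seq_len(nMites)))
  list(genes = genes, mites = mites)
}
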