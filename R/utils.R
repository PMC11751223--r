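#' @import methods
#' @importFrom stats cor pt sd rbinom rpois rnorm runif t.test p.adjust setNames
#' @importFrom utils packageVersion write.table read.delim
NULL

# namespaced logging: informational messages go to stderr via message(),
# so machine-readable outputs on stdout / in files are never polluted.
msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message("[mitescan] ", ...)
}

#' Reverse complement of a nucleotide string
#'
#' Thin character-in/character-out wrapper around
#' [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# derive a reproducible child seed from a master seed, kept within 32-bit
# integer range
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k) %% (.Machine$integer.max - 1L)) + 1L
}

# count character mismatches between two equal-length strings (caller
# guarantees equal length; exact equality is short-circuited for speed)
strMismatches <- function(a, b) {
  if (a == b) return(0L)
  sum(charToRaw(a) != charToRaw(b))
}

# write a data.frame as a plain TSV with optional '#'-prefixed provenance
# header lines (machine output; no quoting, no row names)
writeTsv <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

readTsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
             check.names = FALSE, stringsAsFactors = FALSE)
}
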