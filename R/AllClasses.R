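#' MiteSet: annotated MITE loci with element sequences
#'
#' Container for a set of miniature inverted-repeat transposable elements
#' (MITEs): genomic coordinates as a [GenomicRanges::GRanges] plus the element
#' sequences as a named [Biostrings::DNAStringSet]. Metadata columns on the
#' ranges carry `mite_id`, `family`, `tir_len` (terminal inverted repeat
#' length in bp) and `has_sequence`. Elements listed in the coordinate file
#' but missing from the sequence library are retained and flagged.
#'
#' MITEs are short by definition (typically < 600 bp); a hard cap of 800 bp
#' on element sequence length is enforced by the validity method.
#'
#' @slot ranges GRanges of element loci (1-based closed coordinates).
#' @slot sequences Named DNAStringSet of element sequences.
#'
#' @aliases MiteSet-class
#' @export
setClass("MiteSet",
  representation(ranges = "GRanges", sequences = "DNAStringSet"))

setValidity("MiteSet", function(object) {
  r <- object@ranges
  s <- object@sequences
  errs <- character()
  ids <- S4Vectors::mcols(r)$mite_id
  if (is.null(ids)) return("ranges must carry a 'mite_id' metadata column")
  if (anyDuplicated(ids)) errs <- c(errs, "mite_id values must be unique")
  if (length(s) && any(Biostrings::width(s) > 800))
    errs <- c(errs, "element sequences longer than 800 bp are not MITEs")
  tl <- S4Vectors::mcols(r)$tir_len
  if (!is.null(tl)) {
    known <- ids %in% names(s)
    w <- Biostrings::width(s)[match(ids[known], names(s))]
    if (any(tl[known] < 0 | tl[known] > w / 2, na.rm = TRUE))
      errs <- c(errs, "tir_len must lie in [0, element length / 2]")
  }
  both <- intersect(ids, names(s))
  if (length(both)) {
    wr <- GenomicRanges::width(r)[match(both, ids)]
    ws <- Biostrings::width(s)[match(both, names(s))]
    if (any(wr != ws))
      errs <- c(errs, "locus width must equal element sequence length")
  }
  if (length(errs)) errs else TRUE
})

#' Construct a MiteSet
#'
#' @param ranges GRanges with a `mite_id` metadata column (and optionally
#'   `family`, `tir_len`).
#' @param sequences Named DNAStringSet of element sequences; names must match
#'   `mite_id` values where present.
#' @return A [MiteSet-class] object.
#' @export
MiteSet <- function(ranges, sequences = Biostrings::DNAStringSet()) {
  mc <- S4Vectors::mcols(ranges)
  if (is.null(mc$family)) mc$family <- NA_character_
  if (is.null(mc$tir_len)) mc$tir_len <- NA_integer_
  mc$has_sequence <- mc$mite_id %in% names(sequences)
  S4Vectors::mcols(ranges) <- mc
  new("MiteSet", ranges = ranges, sequences = sequences)
}

#' TipPresenceMatrix: TIP locus genotypes across samples
#'
#' Presence/absence matrix for transposon insertion polymorphism (TIP) loci
#' across samples, as produced by [reconfirmLoci()]. Cells take one of three
#' values: `"present"` (supporting soft-clip evidence found), `"absent"`
#' (locus covered but unsupported) and `"no_data"` (no read coverage at the
#' locus, which is evidence of nothing).
#'
#' @slot loci GRanges of TIP loci (the target-site duplication interval),
#'   with `locus_id` and `mite_id` metadata columns.
#' @slot samples data.frame of sample metadata, one row per column of the
#'   matrix (must contain `sample_id`).
#' @slot presence Character matrix loci x samples.
#'
#' @aliases TipPresenceMatrix-class
#' @export
setClass("TipPresenceMatrix",
  representation(loci = "GRanges", samples = "data.frame",
                 presence = "matrix"))

setValidity("TipPresenceMatrix", function(object) {
  errs <- character()
  if (nrow(object@presence) != length(object@loci))
    errs <- c(errs, "presence matrix rows must match loci")
  if (ncol(object@presence) != nrow(object@samples))
    errs <- c(errs, "presence matrix columns must match samples")
  if (!all(object@presence %in% c("present", "absent", "no_data")))
    errs <- c(errs, "presence values must be present/absent/no_data")
  if (is.null(object@samples$sample_id))
    errs <- c(errs, "samples must contain a sample_id column")
  if (length(errs)) errs else TRUE
})

#' SimulationConfig: conditions for the synthetic study
#'
#' Bundles every tunable of the synthetic-data generator: genome geometry,
#' cohort design, sequencing and bisulfite parameters, methylation model,
#' implanted (non-reference) insertions, and the methylation-phenotype
#' coupling. One master `seed` fixes every downstream draw; equal configs
#' yield byte-identical outputs.
#'
#' Use [simulationConfig()] to build one; presets encode the study designs
#' described in the package vignette.
#'
#' @slot seed Master random seed (integer).
#' @slot genome list: nChroms, chromLength, nGenes, nMites, miteLengthRange,
#'   tirLength, tsdRange, geneLength, heterochromatinFrac, regulatoryFrac.
#' @slot cohort list: lines, generations, repsPerGroup.
#' @slot sequencing list: readLength, depth, perCDepth, minAnchor, mapq,
#'   errorRate.
#' @slot methylation list: background, miteLevelRange, hyperFrac, hypoFrac,
#'   shiftRange, replicateSd.
#' @slot phenotype list: trait, baseline, slope, noiseSd, targetLevelSd,
#'   otherTraits.
#' @slot implants data.frame of implanted insertions (may be empty, in which
#'   case a default scheme is generated per line).
#'
#' @aliases SimulationConfig-class
#' @export
setClass("SimulationConfig",
  representation(seed = "integer", genome = "list", cohort = "list",
                 sequencing = "list", methylation = "list",
                 phenotype = "list", implants = "data.frame"))

setValidity("SimulationConfig", function(object) {
  g <- object@genome; s <- object@sequencing
  errs <- character()
  need <- function(l, k) all(k %in% names(l))
  if (!need(g, c("nChroms", "chromLength", "nGenes", "nMites",
                 "miteLengthRange", "tirLength", "tsdRange")))
    errs <- c(errs, "genome parameters incomplete")
  else {
    if (g$chromLength <= 0 || g$nChroms <= 0)
      errs <- c(errs, "genome dimensions must be positive")
    if (g$miteLengthRange[1] < 2 * g$tirLength)
      errs <- c(errs, "elements must be at least twice the TIR length")
    if (g$miteLengthRange[1] < s$readLength - 10)
      errs <- c(errs, paste0("shortest element must not be shorter than the ",
                             "longest possible junction clip"))
  }
  if (s$readLength <= 0 || s$depth <= 0)
    errs <- c(errs, "read length and depth must be positive")
  if (nrow(object@implants)) {
    imp <- object@implants
    if (any(imp$site < s$readLength |
            imp$site > g$chromLength - s$readLength))
      errs <- c(errs, "implant sites must be >= readLength from chromosome ends")
  }
  if (length(errs)) errs else TRUE
})
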