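#' @rdname MiteSet
#' @param x A MiteSet or TipPresenceMatrix.
#' @export
setGeneric("miteRanges", function(x) standardGeneric("miteRanges"))

#' @rdname MiteSet
#' @export
setGeneric("miteSequences", function(x) standardGeneric("miteSequences"))

#' @rdname MiteSet
#' @export
setGeneric("miteIds", function(x) standardGeneric("miteIds"))

#' @rdname TipPresenceMatrix-class
#' @param x A TipPresenceMatrix.
#' @export
setGeneric("presence", function(x) standardGeneric("presence"))

#' @rdname TipPresenceMatrix-class
#' @export
setGeneric("tipLoci", function(x) standardGeneric("tipLoci"))

#' @rdname TipPresenceMatrix-class
#' @export
setGeneric("tipSamples", function(x) standardGeneric("tipSamples"))

#' @rdname MiteSet
#' @export
setMethod("miteRanges", "MiteSet", function(x) x@ranges)

#' @rdname MiteSet
#' @export
setMethod("miteSequences", "MiteSet", function(x) x@sequences)

#' @rdname MiteSet
#' @export
setMethod("miteIds", "MiteSet",
          function(x) S4Vectors::mcols(x@ranges)$mite_id)

#' @describeIn MiteSet Number of annotated elements.
#' @param x A MiteSet.
#' @export
setMethod("length", "MiteSet", function(x) length(x@ranges))

#' @describeIn MiteSet Subset by index or mite_id.
#' @param i index vector.
#' @param j,drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "MiteSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, miteIds(x))
  r <- x@ranges[i]
  keep <- intersect(S4Vectors::mcols(r)$mite_id, names(x@sequences))
  new("MiteSet", ranges = r, sequences = x@sequences[keep])
})

setMethod("show", "MiteSet", function(object) {
  cat("MiteSet with", length(object), "elements (",
      sum(S4Vectors::mcols(object@ranges)$has_sequence),
      "with sequence )\n")
  if (length(object)) {
    w <- GenomicRanges::width(object@ranges)
    cat("  length range:", min(w), "-", max(w), "bp;",
        length(unique(as.character(GenomeInfoDb::seqnames(object@ranges)))),
        "chromosome(s)\n")
  }
})

#' @rdname TipPresenceMatrix-class
#' @export
setMethod("presence", "TipPresenceMatrix", function(x) x@presence)

#' @rdname TipPresenceMatrix-class
#' @export
setMethod("tipLoci", "TipPresenceMatrix", function(x) x@loci)

#' @rdname TipPresenceMatrix-class
#' @export
setMethod("tipSamples", "TipPresenceMatrix", function(x) x@samples)

setMethod("show", "TipPresenceMatrix", function(object) {
  p <- object@presence
  cat("TipPresenceMatrix:", nrow(p), "loci x", ncol(p), "samples\n")
  cat("  present:", sum(p == "present"), " absent:", sum(p == "absent"),
      " no_data:", sum(p == "no_data"), "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  g <- object@genome; co <- object@cohort
  cat("SimulationConfig (seed ", object@seed, ")\n", sep = "")
  cat("  genome: ", g$nChroms, " chrom x ", g$chromLength, " bp, ",
      g$nGenes, " genes, ", g$nMites, " MITEs\n", sep = "")
  cat("  cohort: ", length(co$lines), " line(s) x ",
      length(co$generations), " generation(s) x 2 groups x ",
      co$repsPerGroup, " replicates\n", sep = "")
  cat("  implants:", nrow(object@implants), "insertion events\n")
})
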