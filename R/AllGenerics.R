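#' @include AllClasses.R
NULL

#' Accessors for seqABC classes
#'
#' Small accessor generics: number of sequences, alignment length, locus
#' label, inheritance mode, sample ids and the raw character matrix of a
#' [SeqAlignment-class]; sequences and counts of a [HaplotypeTable-class].
#'
#' @param x an object.
#' @return the corresponding slot content.
#' @name seqABC-accessors
#' @aliases nSequences seqLength locusName inheritanceMode sampleIDs
#'   alignmentMatrix haplotypeSequences haplotypeCounts
NULL

#' @rdname seqABC-accessors
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))
#' @rdname seqABC-accessors
#' @export
setGeneric("seqLength", function(x) standardGeneric("seqLength"))
#' @rdname seqABC-accessors
#' @export
setGeneric("locusName", function(x) standardGeneric("locusName"))
#' @rdname seqABC-accessors
#' @export
setGeneric("inheritanceMode", function(x) standardGeneric("inheritanceMode"))
#' @rdname seqABC-accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))
#' @rdname seqABC-accessors
#' @export
setGeneric("alignmentMatrix", function(x) standardGeneric("alignmentMatrix"))
#' @rdname seqABC-accessors
#' @export
setGeneric("haplotypeSequences", function(x) standardGeneric("haplotypeSequences"))
#' @rdname seqABC-accessors
#' @export
setGeneric("haplotypeCounts", function(x) standardGeneric("haplotypeCounts"))

#' @rdname seqABC-accessors
setMethod("nSequences", "SeqAlignment", function(x) nrow(x@mat))
#' @rdname seqABC-accessors
setMethod("seqLength", "SeqAlignment", function(x) ncol(x@mat))
#' @rdname seqABC-accessors
setMethod("locusName", "SeqAlignment", function(x) x@locus)
#' @rdname seqABC-accessors
setMethod("inheritanceMode", "SeqAlignment", function(x) x@inheritance)
#' @rdname seqABC-accessors
setMethod("sampleIDs", "SeqAlignment", function(x) rownames(x@mat))
#' @rdname seqABC-accessors
setMethod("alignmentMatrix", "SeqAlignment", function(x) x@mat)

#' @rdname seqABC-accessors
setMethod("nSequences", "HaplotypeTable", function(x) sum(x@counts))
#' @rdname seqABC-accessors
setMethod("locusName", "HaplotypeTable", function(x) x@locus)
#' @rdname seqABC-accessors
setMethod("inheritanceMode", "HaplotypeTable", function(x) x@inheritance)
#' @rdname seqABC-accessors
setMethod("haplotypeSequences", "HaplotypeTable", function(x) x@sequences)
#' @rdname seqABC-accessors
setMethod("haplotypeCounts", "HaplotypeTable", function(x) x@counts)

setMethod("show", "SeqAlignment", function(object) {
  cat(sprintf("SeqAlignment: locus '%s' (%s)\n  %d sequences x %d sites\n",
              object@locus, object@inheritance,
              nrow(object@mat), ncol(object@mat)))
  invisible(object)
})

setMethod("show", "HaplotypeTable", function(object) {
  cat(sprintf(
    "HaplotypeTable: locus '%s'\n  %d haplotypes from %d sequences over %d populations\n",
    object@locus, length(object@sequences), sum(object@counts),
    ncol(object@counts)))
  invisible(object)
})

setMethod("show", "ScenarioModel", function(object) {
  p <- object@populations
  cat(sprintf("ScenarioModel '%s': %d populations (%d sampled, %d ghost), %d events\n",
              object@name, nrow(p), sum(p$sampled), sum(!p$sampled),
              nrow(object@events)))
  if (nrow(object@events)) {
    ev <- object@events
    cat(sprintf("  %s: %s -> %s (founder %s for %s)\n",
                ev$time, ev$source, ev$target, ev$founder, ev$duration),
        sep = "")
  }
  invisible(object)
})

setMethod("show", "ParsimonyNetwork", function(object) {
  g <- object@graph
  memb <- igraph::V(g)$component
  obs <- !igraph::V(g)$is_inferred
  cat(sprintf(
    "ParsimonyNetwork: %d haplotypes (+%d inferred nodes) in %d component(s), limit %d steps\n",
    sum(obs), sum(!obs), length(unique(memb)), object@limit))
  invisible(object)
})

setMethod("show", "ReferenceTable", function(object) {
  cat(sprintf("ReferenceTable: %d simulations, %d scenarios, %d statistics\n",
              length(object@scenario), length(unique(object@scenario)),
              ncol(object@stats)))
  tab <- table(object@scenario)
  cat(sprintf("  %s: %d rows\n", names(tab), as.integer(tab)), sep = "")
  invisible(object)
})

setMethod("show", "StudyDesign", function(object) {
  cat(sprintf("StudyDesign: %d populations in %d demes, %d loci (%s)\n",
              nrow(object@populations),
              length(unique(object@populations$deme)),
              nrow(object@loci),
              paste(object@loci$locus, collapse = ", ")))
  invisible(object)
})
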