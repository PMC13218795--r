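#' Accessors for meiocnv containers
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x a meiocnv S4 object.
#' @return `loci()` and `bins()` return `GRanges`; `baseline()` a character or
#'   numeric baseline; `chromCalls()`/`segCalls()` call `data.frame`s (or NULL
#'   before calling); `gameteCopies()`, `maternalCopies()`,
#'   `paternalCopies()`, `totalCopies()` named integer vectors;
#'   `gameteErrors()` a named character vector; `truthEvents()` the event
#'   table of an [EmbryoTruth-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("loci", function(x) standardGeneric("loci"))
#' @rdname accessors
#' @export
setGeneric("bins", function(x) standardGeneric("bins"))
#' @rdname accessors
#' @export
setGeneric("baseline", function(x) standardGeneric("baseline"))
#' @rdname accessors
#' @export
setGeneric("chromCalls", function(x) standardGeneric("chromCalls"))
#' @rdname accessors
#' @export
setGeneric("segCalls", function(x) standardGeneric("segCalls"))
#' @rdname accessors
#' @export
setGeneric("gameteCopies", function(x) standardGeneric("gameteCopies"))
#' @rdname accessors
#' @export
setGeneric("gameteErrors", function(x) standardGeneric("gameteErrors"))
#' @rdname accessors
#' @export
setGeneric("maternalCopies", function(x) standardGeneric("maternalCopies"))
#' @rdname accessors
#' @export
setGeneric("paternalCopies", function(x) standardGeneric("paternalCopies"))
#' @rdname accessors
#' @export
setGeneric("totalCopies", function(x) standardGeneric("totalCopies"))
#' @rdname accessors
#' @export
setGeneric("truthEvents", function(x) standardGeneric("truthEvents"))
#' @rdname accessors
#' @export
setGeneric("genotypes", function(x, parent) standardGeneric("genotypes"))

#' @rdname accessors
setMethod("loci", "SnpPanel", function(x) x@loci)
#' @rdname accessors
setMethod("loci", "AlleleCountTable", function(x) x@loci)
#' @rdname accessors
setMethod("bins", "BinnedDepthProfile", function(x) x@bins)
#' @rdname accessors
setMethod("bins", "CopyNumberProfile", function(x) x@bins)
#' @rdname accessors
setMethod("baseline", "BinnedDepthProfile", function(x) x@baseline)
#' @rdname accessors
setMethod("baseline", "CopyNumberProfile", function(x) x@baseline)
#' @rdname accessors
setMethod("chromCalls", "CopyNumberProfile", function(x) x@chromCalls)
#' @rdname accessors
setMethod("segCalls", "CopyNumberProfile", function(x) x@segCalls)
#' @rdname accessors
setMethod("gameteCopies", "GameteKaryotype", function(x) x@copies)
#' @rdname accessors
setMethod("gameteErrors", "GameteKaryotype", function(x) x@errors)
#' @rdname accessors
setMethod("maternalCopies", "EmbryoTruth", function(x) x@maternalCopies)
#' @rdname accessors
setMethod("paternalCopies", "EmbryoTruth", function(x) x@paternalCopies)
#' @rdname accessors
setMethod("totalCopies", "EmbryoTruth",
          function(x) x@maternalCopies + x@paternalCopies)
#' @rdname accessors
setMethod("truthEvents", "EmbryoTruth", function(x) x@events)

#' @rdname accessors
#' @param parent `"father"` or `"mother"`.
setMethod("genotypes", "ParentalGenotypes", function(x, parent = c("father", "mother")) {
  parent <- match.arg(parent)
  h <- slot(x, parent)
  c("AA", "AB", "BB")[rowSums(h) + 1L]
})

setMethod("show", "GenomeModel", function(object) {
  cat(sprintf("GenomeModel: %d chromosomes, %.1f Mb total\n",
              length(object@seqlens), sum(object@seqlens) / 1e6))
})

setMethod("show", "SnpPanel", function(object) {
  cat(sprintf("SnpPanel: %d loci on %d chromosomes\n",
              length(object@loci),
              length(unique(as.character(seqnames(object@loci))))))
})

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf(
    "NoiseModel: %.1f reads/bin, NB size %.1f, gcSlope %.2f, dropout %.2f, seqError %.3f\n",
    object@meanReadsPerBin, object@dispersion, object@gcSlope,
    object@dropout, object@seqError))
})

setMethod("show", "ParentalGenotypes", function(object) {
  cat(sprintf("ParentalGenotypes: %d loci (father het %.3f, mother het %.3f)\n",
              length(object@panel@loci),
              mean(rowSums(object@father) == 1L),
              mean(rowSums(object@mother) == 1L)))
})

setMethod("show", "GameteKaryotype", function(object) {
  ab <- sum(object@copies != 1L)
  cat(sprintf("GameteKaryotype: %s%s\n",
              if (object@diploid) "whole-genome diploid"
              else if (ab == 0L) "euploid (1n)"
              else sprintf("%d chromosome(s) with abnormal copy number", ab),
              ""))
})

setMethod("show", "EmbryoTruth", function(object) {
  tot <- totalCopies(object)
  ab <- sum(tot != 2L)
  cat(sprintf("EmbryoTruth: %d whole-chromosome abnormalit%s, %d event row(s)\n",
              ab, if (ab == 1L) "y" else "ies", nrow(object@events)))
})

setMethod("show", "BinnedDepthProfile", function(object) {
  cat(sprintf("BinnedDepthProfile: %d bins, %s baseline, %snormalized\n",
              length(object@bins), object@baseline,
              if (object@normalized) "" else "not "))
})

setMethod("show", "CopyNumberProfile", function(object) {
  nc <- if (is.null(object@chromCalls)) 0L
        else sum(object@chromCalls$event != "none")
  cat(sprintf("CopyNumberProfile: %d bins, baseline %g, %s\n",
              length(object@bins), object@baseline,
              if (is.null(object@chromCalls)) "calls not yet populated"
              else sprintf("%d whole-chromosome event(s)", nc)))
})

setMethod("show", "AlleleCountTable", function(object) {
  d <- object@loci$refCount + object@loci$altCount
  cat(sprintf("AlleleCountTable: %d loci, median depth %g\n",
              length(object@loci), median(d)))
})
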