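#' @title Core S4 classes
#' @name meiocnv-classes
#' @description S4 containers used across the simulation and inference
#'   modules. All genomic coordinates are 0-based half-open; chromosomes are
#'   plain labels from \code{c(1:22, "X", "Y")}.
NULL

setClassUnion("dfOrNULL", c("data.frame", "NULL"))

#' GenomeModel: abstract genome geometry
#'
#' Chromosome lengths and centromere positions for an abstract genome. No
#' sequence is attached; only bin/locus geometry matters because no alignment
#' is ever performed.
#'
#' @slot seqlens named numeric vector of chromosome lengths (bp).
#' @slot centromeres named numeric vector of centromere positions (bp).
#' @exportClass GenomeModel
setClass("GenomeModel",
  representation(seqlens = "numeric", centromeres = "numeric"))

setValidity("GenomeModel", function(object) {
  sl <- object@seqlens; cen <- object@centromeres
  if (is.null(names(sl)) || any(!nzchar(names(sl))))
    return("chromosome lengths must be named")
  if (!identical(names(sl), names(cen)))
    return("centromeres must be named like seqlens")
  if (any(sl <= 0)) return("chromosome lengths must be positive")
  if (any(cen <= 0 | cen >= sl)) return("centromeres must lie inside chromosomes")
  TRUE
})

#' SnpPanel: genome-wide SNP loci with population allele frequencies
#'
#' @slot loci a \code{GRanges} of width-1 loci carrying metadata column
#'   \code{popBaf}, the population B-allele frequency in (0,1).
#' @slot genome the \linkS4class{GenomeModel} the loci live on.
#' @exportClass SnpPanel
setClass("SnpPanel",
  representation(loci = "GRanges", genome = "GenomeModel"))

setValidity("SnpPanel", function(object) {
  gr <- object@loci
  if (length(gr) == 0L) return("panel has no loci")
  if (is.null(gr$popBaf)) return("loci must carry a 'popBaf' column")
  if (any(gr$popBaf < 0 | gr$popBaf > 1))
    return("popBaf must lie within [0,1]")
  if (!all(as.character(seqnames(gr)) %in% names(object@genome@seqlens)))
    return("loci on chromosomes absent from the genome model")
  bychr <- split(start(gr), as.character(seqnames(gr)))
  if (any(vapply(bychr, function(p) is.unsorted(p, strictly = TRUE), logical(1))))
    return("positions must be strictly increasing within a chromosome")
  TRUE
})

#' NoiseModel: sequencing/amplification noise parameters
#'
#' Defaults emulate MDA/PicoPLEX single-cell amplification followed by
#' low-coverage sequencing: negative-binomial bin counts with a monotone GC
#' efficiency curve, per-haplotype allele dropout, and per-read allele flips.
#'
#' @slot meanReadsPerBin expected reads per bin for one baseline copy set.
#' @slot dispersion negative-binomial size (inverse-dispersion); larger is
#'   closer to Poisson.
#' @slot gcSlope slope of the exponential GC efficiency curve
#'   \code{exp(gcSlope * (gc - 0.45))}; monotone in GC.
#' @slot dropout per-locus, per-haplotype allele dropout probability.
#' @slot seqError per-read probability of reporting the opposite allele.
#' @exportClass NoiseModel
setClass("NoiseModel",
  representation(meanReadsPerBin = "numeric", dispersion = "numeric",
                 gcSlope = "numeric", dropout = "numeric", seqError = "numeric"))

setValidity("NoiseModel", function(object) {
  if (object@meanReadsPerBin <= 0) return("meanReadsPerBin must be > 0")
  if (object@dispersion <= 0) return("dispersion (NB size) must be > 0")
  p <- c(object@dropout, object@seqError)
  if (any(p < 0 | p > 1)) return("probabilities must lie in [0,1]")
  TRUE
})

#' ParentalGenotypes: phased biallelic genotypes for a father/mother pair
#'
#' Haplotypes are stored explicitly (0 = A/reference, 1 = B/alternate) so that
#' meiosis can transmit recombinant chromatids; genotypes are derived views.
#'
#' @slot panel the \linkS4class{SnpPanel}.
#' @slot father,mother integer matrices (loci x 2 haplotypes) of 0/1 alleles.
#' @exportClass ParentalGenotypes
setClass("ParentalGenotypes",
  representation(panel = "SnpPanel", father = "matrix", mother = "matrix"))

setValidity("ParentalGenotypes", function(object) {
  n <- length(object@panel@loci)
  for (side in c("father", "mother")) {
    h <- slot(object, side)
    if (!is.matrix(h) || nrow(h) != n || ncol(h) != 2L)
      return(sprintf("%s haplotypes must be a loci x 2 matrix", side))
    if (!all(h %in% c(0L, 1L))) return("haplotype alleles must be 0/1")
  }
  TRUE
})

#' GameteKaryotype: one meiotic product with per-copy allele sequences
#'
#' @slot panel the \linkS4class{SnpPanel}.
#' @slot copies named integer vector, copy count per chromosome.
#' @slot alleles list per chromosome: integer matrix (loci on chromosome x
#'   copies) of 0/1 alleles; zero-column matrix for nullisomy.
#' @slot errors named character per chromosome, one of \code{"none"},
#'   \code{"MI-nondisjunction"}, \code{"MII-nondisjunction"},
#'   \code{"whole-genome-diploidy"}.
#' @slot diploid logical; TRUE for an unreduced (whole-genome diploid) gamete.
#' @exportClass GameteKaryotype
setClass("GameteKaryotype",
  representation(panel = "SnpPanel", copies = "integer", alleles = "list",
                 errors = "character", diploid = "logical"))

setValidity("GameteKaryotype", function(object) {
  chroms <- names(object@panel@genome@seqlens)
  if (!identical(names(object@copies), chroms)) return("copies must cover every chromosome")
  if (!identical(names(object@errors), chroms)) return("errors must cover every chromosome")
  if (any(object@copies < 0L)) return("copy counts must be non-negative")
  ok <- all(object@copies == 1L) && all(object@errors == "none")
  if (!object@diploid && all(object@errors == "none") && !all(object@copies == 1L))
    return("error-free non-diploid gametes must carry one copy of every chromosome")
  if (object@diploid && !all(object@errors == "whole-genome-diploidy"))
    return("whole-genome diploid gametes must be annotated as such on every chromosome")
  for (chr in chroms) {
    m <- object@alleles[[chr]]
    if (!is.matrix(m) || ncol(m) != object@copies[[chr]])
      return("allele matrices must have one column per copy")
  }
  TRUE
})

#' EmbryoTruth: ground-truth karyotype of a simulated embryo
#'
#' @slot panel the \linkS4class{SnpPanel}.
#' @slot maternalCopies,paternalCopies named integer vectors per chromosome.
#' @slot alleles list per chromosome: matrix (loci x total copies) of 0/1.
#' @slot parentOf list per chromosome: \code{"maternal"}/\code{"paternal"}
#'   label per copy column.
#' @slot events data.frame of segmental/mosaic events with columns
#'   \code{chrom,start,end,delta,parent,f}; intervals half-open; \code{f = 1}
#'   denotes a constitutive event.
#' @exportClass EmbryoTruth
setClass("EmbryoTruth",
  representation(panel = "SnpPanel", maternalCopies = "integer",
                 paternalCopies = "integer", alleles = "list",
                 parentOf = "list", events = "data.frame"))

setValidity("EmbryoTruth", function(object) {
  chroms <- names(object@panel@genome@seqlens)
  if (!identical(names(object@maternalCopies), chroms) ||
      !identical(names(object@paternalCopies), chroms))
    return("copy vectors must cover every chromosome")
  tot <- object@maternalCopies + object@paternalCopies
  for (chr in chroms) {
    if (ncol(object@alleles[[chr]]) != tot[[chr]])
      return("total copies must equal maternal + paternal copies")
    po <- object@parentOf[[chr]]
    if (sum(po == "maternal") != object@maternalCopies[[chr]] ||
        sum(po == "paternal") != object@paternalCopies[[chr]])
      return("parent-of-origin labels inconsistent with copy counts")
  }
  ev <- object@events
  if (nrow(ev)) {
    need <- c("chrom", "start", "end", "delta", "parent", "f")
    if (!all(need %in% names(ev))) return("events must have chrom,start,end,delta,parent,f")
    if (any(ev$f < 0 | ev$f > 1)) return("event cell fractions must lie in [0,1]")
    sl <- object@panel@genome@seqlens
    if (any(ev$start < 0 | ev$end > sl[as.character(ev$chrom)] | ev$start >= ev$end))
      return("event intervals must be half-open and inside chromosome bounds")
  }
  TRUE
})

#' BinnedDepthProfile: per-bin read counts along the genome
#'
#' @slot bins non-overlapping sorted \code{GRanges} with metadata columns
#'   \code{gc} (GC fraction) and \code{count} (reads; numeric after
#'   normalization).
#' @slot baseline \code{"diploid"} (embryo) or \code{"haploid"} (sperm).
#' @slot normalized logical; TRUE once GC-normalized.
#' @exportClass BinnedDepthProfile
setClass("BinnedDepthProfile",
  representation(bins = "GRanges", baseline = "character", normalized = "logical"))

setValidity("BinnedDepthProfile", function(object) {
  gr <- object@bins
  if (is.null(gr$gc) || is.null(gr$count)) return("bins need 'gc' and 'count' columns")
  if (any(gr$count < 0)) return("counts must be non-negative")
  if (any(gr$gc < 0 | gr$gc > 1)) return("GC fractions must lie in [0,1]")
  if (!object@baseline %in% c("diploid", "haploid"))
    return("baseline must be 'diploid' or 'haploid'")
  bychr <- split(seq_along(gr), as.character(seqnames(gr)))
  for (idx in bychr) {
    s <- start(gr)[idx]; e <- end(gr)[idx]
    if (is.unsorted(s, strictly = TRUE)) return("bins must be sorted within chromosomes")
    if (any(s[-1] < e[-length(e)] + 1L)) return("bins must not overlap")
  }
  TRUE
})

#' CopyNumberProfile: baseline-relative copy ratios and CNV calls
#'
#' Ratios are on the copy-number scale: 2.0 is the diploid baseline, 1.0 the
#' haploid baseline. Calls carry the estimated abnormal-cell fraction
#' \code{f} and a status assigned by the 30%/70% rule: euploid if
#' \code{f < 0.30}, mosaic if \code{0.30 <= f <= 0.70}, aneuploid if
#' \code{f > 0.70}.
#'
#' @slot bins \code{GRanges} with \code{gc}, \code{count} and \code{ratio}.
#' @slot baseline numeric baseline copy number (2 or 1).
#' @slot chromCalls per-chromosome call table (or NULL before calling).
#' @slot segCalls segmental call table (or NULL before calling).
#' @exportClass CopyNumberProfile
setClass("CopyNumberProfile",
  representation(bins = "GRanges", baseline = "numeric",
                 chromCalls = "dfOrNULL", segCalls = "dfOrNULL"))

setValidity("CopyNumberProfile", function(object) {
  if (is.null(object@bins$ratio)) return("bins need a 'ratio' column")
  if (!object@baseline %in% c(1, 2)) return("baseline must be 1 or 2")
  cc <- object@chromCalls
  if (!is.null(cc) && nrow(cc) &&
      any(!is.na(cc$f) & (cc$f < 0 | cc$f > 1)))
    return("abnormal-cell fractions must lie in [0,1]")
  TRUE
})

#' AlleleCountTable: per-SNP allele read counts plus parental genotypes
#'
#' @slot loci width-1 \code{GRanges} with metadata columns \code{refCount},
#'   \code{altCount} (reads supporting A and B), and \code{fatherGT},
#'   \code{motherGT} in \code{c("AA","AB","BB")}.
#' @exportClass AlleleCountTable
setClass("AlleleCountTable", representation(loci = "GRanges"))

setValidity("AlleleCountTable", function(object) {
  gr <- object@loci
  need <- c("refCount", "altCount", "fatherGT", "motherGT")
  if (!all(need %in% names(mcols(gr))))
    return("loci need refCount, altCount, fatherGT, motherGT")
  if (any(gr$refCount < 0 | gr$altCount < 0)) return("read counts must be non-negative")
  gts <- c("AA", "AB", "BB")
  if (!all(gr$fatherGT %in% gts) || !all(gr$motherGT %in% gts))
    return("parental genotypes must be AA/AB/BB")
  TRUE
})
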