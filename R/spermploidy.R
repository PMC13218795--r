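#' Heterozygosity index
#'
#' `HI = log2(R_sample / R_diploid)`, where the two rates are the
#' heterozygous-call rates of the test cell and of a diploid reference over
#' the same loci. A diploid cell has HI near 0 (balanced heterozygosity); a
#' haploid cell loses its heterozygous calls and drives HI strongly
#' negative. An error-free haploid has `R_sample = 0`, so rates below the
#' floor `eps` are clamped to `eps` and the result flagged (attribute
#' `"clamped"`).
#'
#' @param rSample heterozygous-call rate of the test cell, in \[0,1\].
#' @param rDiploid heterozygous-call rate of the diploid reference, > 0.
#' @param eps floor applied to `rSample` to keep HI finite.
#' @return numeric HI (log2 scale) with logical attribute `"clamped"`.
#' @examples
#' heterozygosityIndex(0.25, 0.5) # -1: haploid-like
#' heterozygosityIndex(0.5, 0.5)  #  0: diploid-like
#' @export
heterozygosityIndex <- function(rSample, rDiploid, eps = 1e-4) {
  stopifnot(length(rSample) == 1L, length(rDiploid) == 1L)
  if (is.na(rDiploid) || rDiploid <= 0)
    stop("invalid reference: R_diploid must be > 0")
  if (rSample < 0 || rSample > 1 || rDiploid > 1)
    stop("heterozygosity rates must lie in [0,1]")
  clamped <- rSample < eps
  hi <- log2(max(rSample, eps) / rDiploid)
  attr(hi, "clamped") <- clamped
  hi
}

#' Heterozygous-call rate from allele counts
#'
#' The fraction of assessable loci (depth at least `minDepth`) whose
#' B-allele read fraction falls within `hetBand`. The band is symmetric
#' around 0.5, so this is equivalent to requiring the minor-allele fraction
#' to exceed the band's lower edge.
#'
#' @param alleleCounts an [AlleleCountTable-class].
#' @param minDepth minimum total reads for a locus to be assessed.
#' @param hetBand inclusive B-allele fraction band counted as heterozygous.
#' @return the heterozygous-call rate with attribute `"nAssessed"`.
#' @export
hetRate <- function(alleleCounts, minDepth = 10L, hetBand = c(0.2, 0.8)) {
  stopifnot(is(alleleCounts, "AlleleCountTable"))
  gr <- alleleCounts@loci
  tot <- gr$refCount + gr$altCount
  assessed <- tot >= minDepth
  if (!any(assessed)) stop("zero assessable loci at this depth threshold")
  baf <- gr$altCount[assessed] / tot[assessed]
  rate <- mean(baf >= hetBand[1] & baf <= hetBand[2])
  attr(rate, "nAssessed") <- sum(assessed)
  rate
}

#' Default thresholds for sperm ploidy calling
#'
#' @param hiHaploid HI at or below which a flat profile is called haploid.
#' @param hiDiploidBand half-width of the HI band around 0 accepted as
#'   diploid.
#' @param flatTol per-chromosome tolerance around ratio 1 for a "flat"
#'   haploid profile.
#' @param doubledRange per-chromosome median-ratio range read as a uniform
#'   genome doubling.
#' @param uniformFrac fraction of chromosomes that must agree for the
#'   flat/doubled patterns.
#' @param cnvSupport minimum fraction of bins backing the CNV pattern for it
#'   to override a conflicting HI.
#' @return named list of thresholds.
#' @export
ploidyThresholds <- function(hiHaploid = -0.7, hiDiploidBand = 0.3,
                             flatTol = 0.3, doubledRange = c(1.6, 2.5),
                             uniformFrac = 0.9, cnvSupport = 0.8) {
  list(hiHaploid = hiHaploid, hiDiploidBand = hiDiploidBand,
       flatTol = flatTol, doubledRange = doubledRange,
       uniformFrac = uniformFrac, cnvSupport = cnvSupport)
}

#' Call single-sperm ploidy from CNV profile plus heterozygosity index
#'
#' Integrates the two lines of evidence: a flat haploid-baseline profile with
#' HI at or below `hiHaploid` is haploid; a uniformly doubled profile with
#' |HI| within `hiDiploidBand` is diploid (this requires ratios against an
#' external haploid reference -- self-median normalization hides uniform
#' doubling). Otherwise the whole-chromosome event count from the CNV calls
#' assigns simple (1-2 events) or complex (3 or more) aneuploidy; event
#' calls already require at least 80% of bins to agree in direction, so the
#' CNV evidence overrides HI in that branch. Irreconcilable evidence (for
#' example a flat profile with a diploid-like HI, or a doubled profile with
#' weak bin support and an out-of-band HI) returns `"ambiguous"` with both
#' evidence lines reported.
#'
#' @param cnv a haploid-baseline [CopyNumberProfile-class] with chromosome
#'   calls populated.
#' @param hi heterozygosity index of the same cell.
#' @param thresholds see [ploidyThresholds()].
#' @return list with `class` (one of haploid, diploid, aneuploid-simple,
#'   aneuploid-complex, ambiguous), `hi`, `eventCount`, `events` (the
#'   aneuploid whole-chromosome call rows), and `evidence` (character
#'   description of both lines).
#' @export
callPloidy <- function(cnv, hi, thresholds = ploidyThresholds()) {
  stopifnot(is(cnv, "CopyNumberProfile"))
  if (cnv@baseline != 1)
    stop("sperm ploidy calling expects a haploid-baseline profile")
  cc <- cnv@chromCalls
  if (is.null(cc)) stop("chromosome calls must be populated first")
  th <- thresholds
  hiVal <- as.numeric(hi)
  ok <- cc$event != "no-call"
  med <- cc$ratioMedian[ok]
  flatFrac <- mean(abs(med - 1) <= th$flatTol)
  doubledFrac <- mean(med >= th$doubledRange[1] & med <= th$doubledRange[2])
  evRows <- cc[ok & cc$event %in% c("gain", "loss") &
                 cc$status %in% "aneuploid", , drop = FALSE]
  nEv <- nrow(evRows)
  # fraction of bins backing the dominant pattern, judged on locally
  # smoothed ratios (per-bin ratios against a single-cell reference are too
  # noisy to vote individually)
  chrOf <- as.character(seqnames(cnv@bins))
  sm <- unlist(lapply(split(cnv@bins$ratio, chrOf), function(r) {
    fin <- is.finite(r)
    if (sum(fin) < 3L) return(r)
    k <- min(15L, sum(fin)); if (k %% 2L == 0L) k <- k - 1L
    r[fin] <- stats::runmed(r[fin], k = max(k, 1L), endrule = "median")
    r
  }), use.names = FALSE)
  r <- sm[is.finite(sm)]
  binFlat <- mean(abs(r - 1) <= th$flatTol)
  binDoubled <- mean(r >= th$doubledRange[1] & r <= th$doubledRange[2])
  evidence <- sprintf(
    "CNV: %.0f%% chromosomes flat, %.0f%% doubled, %d aneuploid event(s); HI = %.3f",
    100 * flatFrac, 100 * doubledFrac, nEv, hiVal)
  cls <- if (flatFrac >= th$uniformFrac) {
    if (hiVal <= th$hiHaploid) "haploid" else "ambiguous"
  } else if (doubledFrac >= th$uniformFrac) {
    if (abs(hiVal) <= th$hiDiploidBand) "diploid"
    else if (binDoubled >= th$cnvSupport) "diploid"
    else "ambiguous"
  } else if (nEv >= 3L) "aneuploid-complex"
  else if (nEv >= 1L) "aneuploid-simple"
  else "ambiguous"
  list(class = cls, hi = hiVal, eventCount = nEv, events = evRows,
       evidence = evidence,
       support = c(binFlat = binFlat, binDoubled = binDoubled))
}

#' FISH aneuploidy frequencies
#'
#' Converts tabulated FISH counts into percentage frequencies of total
#' analyzable nuclei. Disomy is two signals for a given chromosome,
#' nullisomy is absence of signal, and diploidy is two signals for every
#' chromosome of a probe set; each frequency is the category count divided
#' by the probe set's total analyzable nuclei, as a percentage.
#'
#' @param chromCounts data.frame with columns `probeSet`, `chrom`,
#'   `disomy`, `nullisomy` (counts).
#' @param probeTotals data.frame with columns `probeSet`, `total`
#'   (analyzable nuclei) and `diploidy` (count).
#' @return list with `chromFreq` (per-chromosome disomy/nullisomy
#'   percentages plus the implied normal count) and `probeFreq`
#'   (per-probe-set diploidy percentage).
#' @examples
#' fishFrequencies(
#'   data.frame(probeSet = "1/9/6", chrom = "1", disomy = 5, nullisomy = 3),
#'   data.frame(probeSet = "1/9/6", total = 1000, diploidy = 2))
#' @export
fishFrequencies <- function(chromCounts, probeTotals) {
  stopifnot(all(c("probeSet", "chrom", "disomy", "nullisomy") %in%
                  names(chromCounts)),
            all(c("probeSet", "total", "diploidy") %in% names(probeTotals)))
  if (any(probeTotals$total <= 0)) stop("probe-set totals must be > 0")
  tot <- setNames(probeTotals$total, probeTotals$probeSet)
  if (any(!chromCounts$probeSet %in% names(tot)))
    stop("chromCounts reference an unknown probe set")
  n <- tot[as.character(chromCounts$probeSet)]
  if (any(chromCounts$disomy > n | chromCounts$nullisomy > n) ||
      any(probeTotals$diploidy > probeTotals$total))
    stop("category count exceeds probe-set total")
  if (any(chromCounts$disomy < 0) || any(chromCounts$nullisomy < 0) ||
      any(probeTotals$diploidy < 0))
    stop("counts must be non-negative")
  chromFreq <- data.frame(
    probeSet = chromCounts$probeSet, chrom = chromCounts$chrom,
    disomy = chromCounts$disomy, nullisomy = chromCounts$nullisomy,
    normal = as.numeric(n - chromCounts$disomy - chromCounts$nullisomy),
    disomyPct = 100 * chromCounts$disomy / n,
    nullisomyPct = 100 * chromCounts$nullisomy / n)
  probeFreq <- data.frame(
    probeSet = probeTotals$probeSet, total = probeTotals$total,
    diploidy = probeTotals$diploidy,
    diploidyPct = 100 * probeTotals$diploidy / probeTotals$total)
  rownames(chromFreq) <- rownames(probeFreq) <- NULL
  list(chromFreq = chromFreq, probeFreq = probeFreq)
}
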