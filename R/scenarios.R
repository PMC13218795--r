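#' Simulate an embryo with chosen whole-chromosome aneuploidies
#'
#' Builds the two gametes so that each requested event ends up in the
#' transmitted meiotic product: gains use nondisjunction oriented toward
#' the transmitted product (`+`), losses away from it (`-`).
#'
#' @param parents a [ParentalGenotypes-class].
#' @param events data.frame with columns `chrom`, `parent`
#'   (`"maternal"`/`"paternal"`), `type` (`"gain"`/`"loss"`), and
#'   optionally `stage` (`"MI"`/`"MII"`, default MI).
#' @param mosaicEvents passed through to [formEmbryo()].
#' @param seed RNG seed.
#' @return an [EmbryoTruth-class].
#' @examples
#' gm <- genomeModel(c("15", "16", "21", "22"))
#' parents <- simulateParents(snpPanel(gm, 150, seed = 1), seed = 1)
#' ev <- data.frame(chrom = c("16", "21"), parent = "maternal",
#'                  type = c("gain", "loss"))
#' truth <- simulateAneuploidEmbryo(parents, ev, seed = 5)
#' totalCopies(truth)[c("16", "21")] # 3 and 1
#' @export
simulateAneuploidEmbryo <- function(parents, events, mosaicEvents = NULL,
                                    seed = NULL) {
  stopifnot(all(c("chrom", "parent", "type") %in% names(events)))
  if (is.null(events$stage)) events$stage <- "MI"
  stopifnot(all(events$parent %in% c("maternal", "paternal")),
            all(events$type %in% c("gain", "loss")),
            all(events$stage %in% c("MI", "MII")),
            !anyDuplicated(paste(events$chrom, events$parent)))
  specFor <- function(side) {
    ev <- events[events$parent == side, , drop = FALSE]
    if (!nrow(ev)) return(character(0))
    setNames(paste0(ev$stage, ifelse(ev$type == "gain", "+", "-")),
             as.character(ev$chrom))
  }
  withSeed(seed, {
    egg <- simulateGamete(parents, "mother", errorSpec = specFor("maternal"),
                          product = 1L)
    sperm <- simulateGamete(parents, "father", errorSpec = specFor("paternal"),
                            product = 1L)
    formEmbryo(sperm, egg, mosaicEvents = mosaicEvents)
  })
}

#' Simulate one sperm cell of a given ploidy class
#'
#' Scenario presets for the sperm-phenotype classes: `"haploid"` (normal
#' meiotic product), `"diploid"` (unreduced gamete, as seen in
#' macrocephalic sperm), `"aneuploid-complex"` (3 or more chromosomes with
#' random MI/MII nondisjunction, as seen in microcephalic sperm) and
#' `"aneuploid-simple"` (1-2 such chromosomes). These are phenomenological
#' presets; no mechanistic claim links head morphology to error type.
#'
#' @param parents the donor's [ParentalGenotypes-class] (the `father` side
#'   is used).
#' @param class ploidy class to simulate.
#' @param nErrors number of error chromosomes for the aneuploid classes
#'   (default: 1-2 for simple, 3-6 for complex, drawn at random).
#' @param seed RNG seed.
#' @return list with `gamete` ([GameteKaryotype-class]) and `class`.
#' @export
simulateSpermCell <- function(parents,
                              class = c("haploid", "diploid",
                                        "aneuploid-complex",
                                        "aneuploid-simple"),
                              nErrors = NULL, seed = NULL) {
  class <- match.arg(class)
  chroms <- names(parents@panel@genome@seqlens)
  withSeed(seed, {
    g <- switch(class,
      haploid = simulateGamete(parents, "father", product = sample(4L, 1L)),
      diploid = simulateGamete(parents, "father",
                               wholeGenomeDiploidy = TRUE, product = 1L),
      {
        k <- nErrors %||% if (class == "aneuploid-complex")
          sample(3:6, 1L) else sample(1:2, 1L)
        errChr <- sample(chroms, k)
        spec <- setNames(paste0(sample(c("MI", "MII"), k, replace = TRUE),
                                sample(c("+", "-"), k, replace = TRUE)),
                         errChr)
        simulateGamete(parents, "father", errorSpec = spec, product = 1L)
      })
    list(gamete = g, class = class)
  })
}

#' A somatic diploid cell of one parent
#'
#' Returns the parent's own two-homolog genome as a diploid cell (no
#' meiosis, so no crossover-driven loss of heterozygosity), usable as the
#' diploid reference sample of the heterozygosity-index ratio.
#'
#' @param parents a [ParentalGenotypes-class].
#' @param side `"father"` or `"mother"`.
#' @return a [GameteKaryotype-class] with two copies of every chromosome.
#' @export
somaticDiploidCell <- function(parents, side = c("father", "mother")) {
  side <- match.arg(side)
  panel <- parents@panel
  hap <- slot(parents, side)
  chroms <- names(panel@genome@seqlens)
  idx <- .lociByChrom(panel)
  alleles <- lapply(chroms, function(chr) hap[idx[[chr]], , drop = FALSE])
  names(alleles) <- chroms
  new("GameteKaryotype", panel = panel,
      copies = setNames(rep(2L, length(chroms)), chroms), alleles = alleles,
      errors = setNames(rep("whole-genome-diploidy", length(chroms)),
                        chroms),
      diploid = TRUE)
}

#' Reference profiles for the sperm pipeline
#'
#' `spermDepthReference()` simulates `nCells` haploid control cells on the
#' same bins and returns their averaged GC-normalized depth profile (the
#' haploid reference the copy ratios are computed against; averaging
#' several control cells mirrors calibration against a set of control
#' datasets and keeps reference sampling noise out of the per-bin ratios).
#' `diploidHetReference()` pushes a somatic diploid cell of the same donor
#' through the same amplification noise and returns its heterozygous-call
#' rate -- processing the reference like the test cells makes the
#' dropout-induced loss of heterozygosity cancel in the HI ratio.
#'
#' @param parents the donor's [ParentalGenotypes-class].
#' @param binsGr sperm bins (20-kb) from [binGenome()].
#' @param noise a [NoiseModel-class].
#' @param nCells control cells averaged into the depth reference.
#' @param meanDepth per-locus depth for the allele counts.
#' @param seed RNG seed.
#' @return a normalized [BinnedDepthProfile-class]
#'   (`spermDepthReference`) or a numeric het rate
#'   (`diploidHetReference`).
#' @export
spermDepthReference <- function(parents, binsGr, noise = noiseModel(),
                                nCells = 8L, seed = NULL) {
  withSeed(seed, {
    profs <- lapply(seq_len(nCells), function(i) {
      ctrl <- simulateGamete(parents, "father", product = 1L)
      bins(gcNormalize(simulateBinDepth(ctrl, binsGr, noise)))$count
    })
    gr <- granges(binsGr)
    gr$gc <- binsGr$gc
    gr$count <- Reduce(`+`, profs) / nCells
    new("BinnedDepthProfile", bins = gr, baseline = "haploid",
        normalized = TRUE)
  })
}

#' @rdname spermDepthReference
#' @export
diploidHetReference <- function(parents, noise = noiseModel(),
                                meanDepth = 30, seed = NULL) {
  withSeed(seed, {
    dip <- somaticDiploidCell(parents, "father")
    act <- simulateAlleleCounts(dip, parents, noise, meanDepth = meanDepth)
    as.numeric(hetRate(act))
  })
}

#' Run the full sperm pipeline on one cell
#'
#' Depth simulation consumers: GC normalization, copy ratios against the
#' haploid reference, chromosome calls, heterozygous-call rate, HI, and the
#' integrated ploidy call.
#'
#' @param gamete a [GameteKaryotype-class].
#' @param parents the donor's [ParentalGenotypes-class].
#' @param binsGr sperm bins.
#' @param reference normalized haploid reference profile
#'   ([spermDepthReference()]).
#' @param refHetRate diploid-reference het rate ([diploidHetReference()]).
#' @param noise a [NoiseModel-class].
#' @param meanDepth per-locus allele-count depth.
#' @param seed RNG seed.
#' @param thresholds see [ploidyThresholds()].
#' @return the [callPloidy()] result, with the CNV profile attached as
#'   `cnv`.
#' @export
analyzeSperm <- function(gamete, parents, binsGr, reference, refHetRate,
                         noise = noiseModel(), meanDepth = 30, seed = NULL,
                         thresholds = ploidyThresholds()) {
  withSeed(seed, {
    prof <- gcNormalize(simulateBinDepth(gamete, binsGr, noise))
    cn <- callChromosomeCNVs(copyRatioProfile(prof, reference))
    act <- simulateAlleleCounts(gamete, parents, noise, meanDepth = meanDepth)
    hi <- heterozygosityIndex(as.numeric(hetRate(act)), refHetRate)
    out <- callPloidy(cn, hi, thresholds)
    out$cnv <- cn
    out
  })
}
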