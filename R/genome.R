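# hg19-like chromosome lengths (bp), used scaled by default.
.HG19_LENGTHS <- c(
  "1" = 249250621, "2" = 243199373, "3" = 198022430, "4" = 191154276,
  "5" = 180915260, "6" = 171115067, "7" = 159138663, "8" = 146364022,
  "9" = 141213431, "10" = 135534747, "11" = 135006516, "12" = 133851895,
  "13" = 115169878, "14" = 107349540, "15" = 102531392, "16" = 90354753,
  "17" = 81195210, "18" = 78077248, "19" = 59128983, "20" = 63025520,
  "21" = 48129895, "22" = 51304566, "X" = 155270560, "Y" = 59373566)

#' Build an abstract genome model
#'
#' Returns an abstract genome with hg19-like chromosome lengths, scaled by
#' `scale` (default 0.1, i.e. a ~310 Mb genome). Coordinates are 0-based
#' half-open. Centromeres default to the chromosome midpoint; they only
#' matter for the meiosis-I vs meiosis-II allelic signature, which is
#' enforced centromere-proximally.
#'
#' @param chromosomes character vector drawn from `c(1:22, "X", "Y")`.
#' @param scale multiplicative length scale applied to hg19-like lengths.
#' @param centromeres optional named numeric vector of centromere positions
#'   (bp, on the scaled genome); default mid-chromosome.
#' @return a [GenomeModel-class].
#' @examples
#' gm <- genomeModel(chromosomes = c("1", "2", "21"))
#' @export
genomeModel <- function(chromosomes = names(.HG19_LENGTHS), scale = 0.1,
                        centromeres = NULL) {
  chromosomes <- as.character(chromosomes)
  bad <- setdiff(chromosomes, names(.HG19_LENGTHS))
  if (length(bad)) stop("unknown chromosome id: ", paste(bad, collapse = ", "))
  sl <- round(.HG19_LENGTHS[chromosomes] * scale)
  if (is.null(centromeres)) centromeres <- round(sl / 2)
  centromeres <- centromeres[names(sl)]
  new("GenomeModel", seqlens = sl, centromeres = centromeres)
}

#' Tile a genome into fixed-size bins with a synthetic GC landscape
#'
#' Bins the genome into `binSize`-bp windows and attaches a smoothly varying
#' GC fraction per bin (a low-frequency sinusoid plus jitter, clipped to
#' [0.25, 0.65]). The GC landscape is a fixed property of the genome: it is
#' drawn once from `seed` and should be reused across cells of the same
#' experiment.
#'
#' @param genome a [GenomeModel-class].
#' @param binSize bin width in bp (10000 for embryos, 20000 for sperm).
#' @param seed RNG seed for the GC landscape.
#' @param flatGC if TRUE all bins get GC 0.45 (no bias).
#' @return a `GRanges` of bins with metadata column `gc`.
#' @export
binGenome <- function(genome, binSize, seed = 1L, flatGC = FALSE) {
  stopifnot(is(genome, "GenomeModel"), binSize > 0)
  sl <- genome@seqlens
  pieces <- lapply(names(sl), function(chr) {
    s <- seq(0, sl[[chr]] - 1, by = binSize)
    e <- pmin(s + binSize, sl[[chr]])
    GRanges(chr, IRanges(start = s + 1L, end = e))
  })
  gr <- suppressWarnings(do.call(c, pieces))
  if (flatGC) {
    gr$gc <- rep(0.45, length(gr))
    return(gr)
  }
  gr$gc <- withSeed(seed, {
    phase <- runif(length(sl), 0, 2 * pi)
    names(phase) <- names(sl)
    mid <- (start(gr) + end(gr)) / 2
    chr <- as.character(seqnames(gr))
    gc <- 0.43 + 0.08 * sin(2 * pi * 3 * mid / unname(sl[chr]) +
                              unname(phase[chr])) +
      rnorm(length(gr), 0, 0.015)
    unname(pmin(pmax(gc, 0.25), 0.65))
  })
  gr
}

#' Simulate a genome-wide SNP panel
#'
#' Draws `nPerChrom` loci per chromosome at uniform-random positions with
#' population B-allele frequencies from Uniform(0.1, 0.9). With the default
#' density, roughly 4% of loci per chromosome end up informative (both
#' parents homozygous, discordant) for a random couple.
#'
#' @param genome a [GenomeModel-class].
#' @param nPerChrom loci per chromosome.
#' @param seed RNG seed.
#' @return a [SnpPanel-class].
#' @examples
#' panel <- snpPanel(genomeModel(c("1", "2")), nPerChrom = 100, seed = 1)
#' @export
snpPanel <- function(genome, nPerChrom = 1200, seed = 1L) {
  stopifnot(is(genome, "GenomeModel"), nPerChrom >= 1)
  sl <- genome@seqlens
  withSeed(seed, {
    pieces <- lapply(names(sl), function(chr) {
      pos <- sort(sample.int(sl[[chr]] - 1L, nPerChrom)) # distinct, increasing
      gr <- GRanges(chr, IRanges(start = pos + 1L, width = 1L))
      gr$popBaf <- runif(nPerChrom, 0.1, 0.9)
      gr
    })
    new("SnpPanel", loci = suppressWarnings(do.call(c, pieces)), genome = genome)
  })
}

#' Construct a noise model
#'
#' Defaults match the per-bin depth of ~10M single-end reads over 10-kb bins
#' (embryos) and ~5M reads over 20-kb bins (sperm): about 32 reads per bin at
#' the baseline copy number, with MDA-like allele dropout of 0.1 per
#' haplotype for single cells (use `dropout = 0` for bulk parental DNA).
#'
#' @param meanReadsPerBin expected reads per bin at the baseline copy number.
#' @param dispersion negative-binomial size; per-bin CV at mean 32 is ~0.24.
#' @param gcSlope slope of the exponential GC efficiency curve.
#' @param dropout per-locus per-haplotype allele dropout probability.
#' @param seqError per-read allele flip probability.
#' @return a [NoiseModel-class].
#' @export
noiseModel <- function(meanReadsPerBin = 32, dispersion = 40, gcSlope = 1,
                       dropout = 0.1, seqError = 0.01) {
  new("NoiseModel", meanReadsPerBin = meanReadsPerBin, dispersion = dispersion,
      gcSlope = gcSlope, dropout = dropout, seqError = seqError)
}

#' A noise-free model (no dropout, no sequencing error, near-Poisson depth)
#' @param meanReadsPerBin expected reads per bin at the baseline copy number.
#' @return a [NoiseModel-class] with dropout and sequencing error set to zero.
#' @export
noiselessModel <- function(meanReadsPerBin = 32) {
  noiseModel(meanReadsPerBin = meanReadsPerBin, dispersion = 1e6, gcSlope = 0,
             dropout = 0, seqError = 0)
}

# split locus indices by chromosome, in genome chromosome order
.lociByChrom <- function(panel) {
  chr <- as.character(seqnames(panel@loci))
  chroms <- names(panel@genome@seqlens)
  idx <- split(seq_along(chr), factor(chr, levels = chroms))
  idx
}
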