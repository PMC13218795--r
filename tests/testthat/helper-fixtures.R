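# Shared small fixtures, built once per test run.

# six-chromosome genome (~122 Mb scaled), moderately dense panel
fixGenome <- genomeModel(as.character(c(1, 2, 14, 15, 16, 21)))
fixPanel <- snpPanel(fixGenome, nPerChrom = 900, seed = 101)
fixParents <- simulateParents(fixPanel, seed = 102)
fixBins <- binGenome(fixGenome, 1e4, seed = 103)

# a uniform-frequency panel for closed-form Hardy-Weinberg checks
flatPanel <- local({
  gr <- loci(snpPanel(genomeModel("1"), nPerChrom = 10000, seed = 104))
  gr$popBaf <- rep(0.5, length(gr))
  new("SnpPanel", loci = gr, genome = genomeModel("1"))
})

# panel-order helpers
chromOf <- function(panel) as.character(GenomicRanges::seqnames(loci(panel)))

# build a CopyNumberProfile with constant per-chromosome ratios, bypassing
# depth simulation (for boundary/threshold tests)
constantRatioProfile <- function(ratios, baseline = 2, nBins = 60,
                                 binSize = 1e5) {
  grs <- lapply(names(ratios), function(chr) {
    s <- seq(0, (nBins - 1) * binSize, by = binSize)
    gr <- GenomicRanges::GRanges(chr, IRanges::IRanges(start = s + 1,
                                                       width = binSize))
    gr$gc <- rep(0.45, nBins)
    gr$count <- rep(100, nBins)
    gr$ratio <- rep(ratios[[chr]], nBins)
    gr
  })
  gr <- suppressWarnings(do.call(c, grs))
  new("CopyNumberProfile", bins = gr, baseline = baseline,
      chromCalls = NULL, segCalls = NULL)
}

# swap the parental labels everywhere in an allele-count table
swapParentsInTable <- function(act) {
  gr <- loci(act)
  f <- gr$fatherGT
  gr$fatherGT <- gr$motherGT
  gr$motherGT <- f
  new("AlleleCountTable", loci = gr)
}
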