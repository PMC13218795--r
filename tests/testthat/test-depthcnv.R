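test_that("GC normalization removes an injected trend and preserves ratios", {
  # constant GC: normalization must be a pure rescaling
  flat <- binGenome(fixGenome, 1e4, flatGC = TRUE)
  emb <- formEmbryo(simulateGamete(fixParents, "father", seed = 1),
                    simulateGamete(fixParents, "mother", seed = 2))
  prof <- simulateBinDepth(emb, flat, noiselessModel(), seed = 3)
  norm <- gcNormalize(prof)
  cnt <- bins(prof)$count
  ncnt <- bins(norm)$count
  pos <- cnt > 0
  expect_lt(diff(range(ncnt[pos] / cnt[pos])), 1e-9)
  expect_equal(median(ncnt[pos]), median(cnt[pos]), tolerance = 1e-8)

  # counts proportional to GC with flat truth: per-chromosome means equalize
  gr <- binGenome(fixGenome, 1e4, seed = 4)
  lin <- gr
  lin$count <- round(200 * lin$gc)
  linProf <- new("BinnedDepthProfile", bins = lin, baseline = "diploid",
                 normalized = FALSE)
  linNorm <- gcNormalize(linProf)
  chr <- as.character(GenomicRanges::seqnames(gr))
  mns <- tapply(bins(linNorm)$count, chr, mean)
  expect_lt(max(mns) / min(mns), 1.02)

  # on simulated data with the default GC curve, normalization reduces the
  # copy-ratio error against truth
  noisy <- simulateBinDepth(emb, fixBins, noiseModel(), seed = 5)
  rmse <- function(p) {
    r <- 2 * bins(p)$count / median(bins(p)$count[bins(p)$count > 0])
    sqrt(mean((r - 2)^2))
  }
  expect_lt(rmse(gcNormalize(noisy)), rmse(noisy))
})

test_that("GC normalization rejects degenerate input", {
  few <- binGenome(genomeModel("21", scale = 0.002), 1e4, seed = 1)
  zero <- few
  zero$count <- rep(0, length(zero))
  prof <- new("BinnedDepthProfile", bins = zero, baseline = "diploid",
              normalized = FALSE)
  expect_error(gcNormalize(prof), "at least 200 bins|all-zero")
})

test_that("copy ratios sit on the baseline scale", {
  emb <- formEmbryo(simulateGamete(fixParents, "father", seed = 11),
                    simulateGamete(fixParents, "mother", seed = 12))
  prof <- gcNormalize(simulateBinDepth(emb, fixBins, noiseModel(), seed = 13))
  # profile against itself: ratio exactly 2 everywhere (diploid baseline)
  self <- copyRatioProfile(prof, reference = prof)
  expect_true(all(abs(bins(self)$ratio - 2) < 1e-9))

  # embryo trisomy vs ground truth: ratio near 3 on the trisomic chromosome
  tri <- simulateAneuploidEmbryo(fixParents,
                                 data.frame(chrom = "16", parent = "maternal",
                                            type = "gain"), seed = 14)
  triProf <- gcNormalize(simulateBinDepth(tri, fixBins, noiseModel(),
                                          seed = 15))
  cn <- copyRatioProfile(triProf, reference = prof)
  chr <- as.character(GenomicRanges::seqnames(bins(cn)))
  expect_lt(abs(median(bins(cn)$ratio[chr == "16"], na.rm = TRUE) - 3), 0.15)

  # sperm: duplicated chromosome reads as a 1 -> 2 gain on haploid baseline
  ref <- spermDepthReference(fixParents, fixBins, seed = 16)
  dup <- simulateGamete(fixParents, "father", errorSpec = c("15" = "MI+"),
                        seed = 17, product = 1L)
  dupProf <- gcNormalize(simulateBinDepth(dup, fixBins, noiseModel(),
                                          seed = 18))
  cnS <- copyRatioProfile(dupProf, reference = ref)
  chrS <- as.character(GenomicRanges::seqnames(bins(cnS)))
  expect_lt(abs(median(bins(cnS)$ratio[chrS == "15"], na.rm = TRUE) - 2), 0.15)

  # mismatched reference bins are refused
  other <- gcNormalize(simulateBinDepth(emb, binGenome(fixGenome, 2e4,
                                                       seed = 19),
                                        noiseModel(), seed = 20))
  expect_error(copyRatioProfile(prof, reference = other), "bin mismatch")
  expect_error(copyRatioProfile(simulateBinDepth(emb, fixBins, noiseModel(),
                                                 seed = 21)),
               "normalized")
})

test_that("cell-fraction thresholds behave exactly at the class boundaries", {
  ratios <- c("1" = 2.29, "2" = 2.30, "14" = 2.70, "15" = 2.71,
              "16" = 3.0, "21" = 2.5)
  cn <- callChromosomeCNVs(constantRatioProfile(ratios))
  cc <- chromCalls(cn)
  rownames(cc) <- cc$chrom
  expect_identical(cc["1", "status"], "euploid")
  expect_identical(cc["1", "event"], "none")
  expect_identical(cc["2", "status"], "mosaic")
  expect_identical(cc["2", "event"], "gain")
  expect_identical(cc["14", "status"], "mosaic")
  expect_identical(cc["15", "status"], "aneuploid")
  expect_identical(cc["16", "status"], "aneuploid")
  expect_equal(cc["16", "f"], 1)
  expect_equal(cc["21", "f"], 0.5)
  expect_identical(cc["21", "status"], "mosaic")
  expect_equal(cc["2", "f"], 0.3)
  expect_equal(cc["14", "f"], 0.7)
})

test_that("short chromosomes yield a no-call with a warning", {
  gr <- GenomicRanges::GRanges("21", IRanges::IRanges(
    start = seq(1, 5e5, by = 1e5), width = 1e5))
  gr$gc <- rep(0.45, 5)
  gr$count <- rep(100, 5)
  gr$ratio <- rep(2, 5)
  cn <- new("CopyNumberProfile", bins = gr, baseline = 2,
            chromCalls = NULL, segCalls = NULL)
  expect_warning(out <- callChromosomeCNVs(cn), "no-call")
  expect_identical(chromCalls(out)$event, "no-call")
})

test_that("segmental events are recovered and not duplicated", {
  # flat profile: no segmental calls
  emb <- formEmbryo(simulateGamete(fixParents, "father", seed = 31),
                    simulateGamete(fixParents, "mother", seed = 32))
  ref <- gcNormalize(simulateBinDepth(emb, fixBins, noiselessModel(),
                                      seed = 30))
  flatCn <- callSegmentalCNVs(callChromosomeCNVs(
    copyRatioProfile(gcNormalize(simulateBinDepth(emb, fixBins, noiseModel(),
                                                  seed = 33)), ref)),
    minLenBp = 1e6)
  expect_identical(nrow(segCalls(flatCn)), 0L)

  # injected 2-Mb constitutive single-copy gain (a 20-Mb event on the
  # unscaled genome): one call overlapping >= 90% of the true interval
  ev <- data.frame(chrom = "1", start = 5e6, end = 7e6, delta = 1,
                   parent = "maternal", f = 1)
  segEmb <- formEmbryo(simulateGamete(fixParents, "father", seed = 34),
                       simulateGamete(fixParents, "mother", seed = 35),
                       mosaicEvents = ev)
  segCn <- callSegmentalCNVs(callChromosomeCNVs(
    copyRatioProfile(gcNormalize(simulateBinDepth(segEmb, fixBins,
                                                  noiseModel(), seed = 36)),
                     ref)), minLenBp = 1e6)
  sc <- segCalls(segCn)
  expect_identical(nrow(sc), 1L)
  expect_identical(sc$event, "gain")
  overlap <- min(sc$end, 7e6) - max(sc$start, 5e6)
  expect_gt(overlap / 2e6, 0.9)

  # a whole-chromosome event is absorbed by the chromosome-level call
  tri <- simulateAneuploidEmbryo(fixParents,
                                 data.frame(chrom = "16", parent = "maternal",
                                            type = "gain"), seed = 37)
  triCn <- callSegmentalCNVs(callChromosomeCNVs(
    copyRatioProfile(gcNormalize(simulateBinDepth(tri, fixBins, noiseModel(),
                                                  seed = 38)), ref)),
    minLenBp = 1e6)
  expect_identical(chromCalls(triCn)[chromCalls(triCn)$chrom == "16",
                                     "event"], "gain")
  expect_false("16" %in% segCalls(triCn)$chrom)
})

test_that("estimated cell fraction is monotone in the true fraction", {
  emb0 <- formEmbryo(simulateGamete(fixParents, "father", seed = 40),
                     simulateGamete(fixParents, "mother", seed = 41))
  ref <- gcNormalize(simulateBinDepth(emb0, fixBins, noiselessModel(),
                                      seed = 42))
  fGrid <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  fhat <- vapply(seq_along(fGrid), function(i) {
    ev <- data.frame(chrom = "2", start = 0, end = fixGenome@seqlens[["2"]],
                     delta = 1, parent = "maternal", f = fGrid[i])
    reps <- vapply(1:5, function(r) {
      emb <- formEmbryo(simulateGamete(fixParents, "father", seed = 400 + r),
                        simulateGamete(fixParents, "mother", seed = 500 + r),
                        mosaicEvents = ev)
      cn <- copyRatioProfile(gcNormalize(simulateBinDepth(
        emb, fixBins, noiseModel(), seed = 600 + 10 * i + r)), ref)
      chr <- as.character(GenomicRanges::seqnames(bins(cn)))
      abs(median(bins(cn)$ratio[chr == "2"], na.rm = TRUE) - 2)
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  expect_true(all(diff(fhat) > 0))
  expect_lt(max(abs(fhat - fGrid)), 0.08)
})

test_that("embryo classification follows the event-count rules", {
  mk <- function(ratios) callChromosomeCNVs(constantRatioProfile(ratios))
  allTwo <- mk(c("1" = 2, "2" = 2, "14" = 2))
  expect_identical(classifyEmbryo(allTwo)$class, "E")
  sa <- mk(c("1" = 3, "2" = 1, "14" = 2))
  expect_identical(classifyEmbryo(sa)$class, "SA")
  expect_identical(classifyEmbryo(sa)$wholeChromCount, 2L)
  ca <- mk(c("1" = 3, "2" = 1, "14" = 3, "15" = 2))
  expect_identical(classifyEmbryo(ca)$class, "CA")
  # whole-chromosome mosaics and segmentals do not count toward SA/CA
  mosaic <- mk(c("1" = 2.5, "2" = 2))
  expect_identical(classifyEmbryo(mosaic)$class, "other")
  segOnly <- mk(c("1" = 2, "2" = 2))
  segOnly@segCalls <- data.frame(chrom = "1", start = 0, end = 1.5e6,
                                 nBins = 15, event = "loss",
                                 ratioMedian = 1, f = 1,
                                 status = "aneuploid")
  expect_identical(classifyEmbryo(segOnly)$class, "other")
  # sex chromosomes are excluded from the count by default
  sex <- mk(c("1" = 3, "X" = 1, "Y" = 1))
  expect_identical(classifyEmbryo(sex)$class, "SA")
  expect_identical(classifyEmbryo(sex, excludeChroms = character(0))$class,
                   "CA")
  # pure function of the call set
  expect_identical(classifyEmbryo(ca), classifyEmbryo(ca))
})
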