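test_that("parental genotypes follow Hardy-Weinberg expectations", {
  # closed form: heterozygote fraction 2pq = 0.5 at p = 0.5
  parents <- simulateParents(flatPanel, seed = 7)
  for (side in c("father", "mother")) {
    het <- mean(genotypes(parents, side) == "AB")
    se <- sqrt(0.5 * 0.5 / 10000)
    expect_lt(abs(het - 0.5), 4 * se)
  }

  # degenerate frequencies pin the genotype
  gr <- loci(flatPanel)
  gr$popBaf <- rep(c(0, 1), length.out = length(gr))
  degPanel <- new("SnpPanel", loci = gr, genome = genomeModel("1"))
  deg <- simulateParents(degPanel, seed = 8)
  expect_true(all(genotypes(deg, "father")[gr$popBaf == 0] == "AA"))
  expect_true(all(genotypes(deg, "mother")[gr$popBaf == 1] == "BB"))
})

test_that("simulation is deterministic under a fixed seed", {
  a <- simulateParents(fixPanel, seed = 11)
  b <- simulateParents(fixPanel, seed = 11)
  expect_identical(a, b)
  g1 <- simulateGamete(a, "mother", errorSpec = c("16" = "MI"), seed = 3)
  g2 <- simulateGamete(b, "mother", errorSpec = c("16" = "MI"), seed = 3)
  expect_identical(g1, g2)
  p1 <- simulateBinDepth(formEmbryo(g1, g1), fixBins, noiseModel(), seed = 4)
  p2 <- simulateBinDepth(formEmbryo(g2, g2), fixBins, noiseModel(), seed = 4)
  expect_identical(bins(p1)$count, bins(p2)$count)
})

test_that("MI and MII nondisjunction leave the expected allelic signatures", {
  # without crossover the four products are exactly the parental chromatids,
  # so the expected signatures can be enumerated: an MI-disomic product
  # carries one chromatid of each homolog (heterozygous wherever the parent
  # is), an MII-disomic product carries two sister chromatids (homozygous
  # everywhere)
  hap <- slot(fixParents, "mother")
  hetLoci <- rowSums(hap) == 1L
  chr <- chromOf(fixPanel)

  gMI <- simulateGamete(fixParents, "mother", errorSpec = c("16" = "MI+"),
                        crossovers = 0L, seed = 21, product = 1L)
  expect_identical(gameteCopies(gMI)[["16"]], 2L)
  A <- gMI@alleles[["16"]]
  onChr <- chr == "16"
  expect_true(all((A[, 1] != A[, 2]) == hetLoci[onChr]))
  expect_identical(gameteErrors(gMI)[["16"]], "MI-nondisjunction")

  gMII <- simulateGamete(fixParents, "mother", errorSpec = c("16" = "MII+"),
                         crossovers = 0L, seed = 22, product = 1L)
  expect_identical(gameteCopies(gMII)[["16"]], 2L)
  B <- gMII@alleles[["16"]]
  expect_true(all(B[, 1] == B[, 2]))

  # with one crossover the signature still holds centromere-proximally
  gMIx <- simulateGamete(fixParents, "mother", errorSpec = c("16" = "MI+"),
                         crossovers = 1L, seed = 23, product = 1L)
  cen <- fixGenome@centromeres[["16"]]
  pos <- GenomicRanges::start(loci(fixPanel))[onChr]
  nearCen <- abs(pos - cen) < 0.1 * fixGenome@seqlens[["16"]]
  Ax <- gMIx@alleles[["16"]]
  expect_true(all((Ax[nearCen, 1] != Ax[nearCen, 2]) ==
                    hetLoci[onChr][nearCen]))
})

test_that("tetrad conservation holds under random error annotations", {
  tiny <- snpPanel(genomeModel(as.character(c(1, 2, 21, 22)), scale = 0.02),
                   nPerChrom = 6, seed = 31)
  tinyParents <- simulateParents(tiny, seed = 32)
  chroms <- names(tiny@genome@seqlens)
  withr::with_seed(33, {
    for (i in 1:400) {
      k <- sample(0:3, 1)
      spec <- if (k > 0)
        setNames(sample(c("MI", "MII", "MI+", "MII-"), k, replace = TRUE),
                 sample(chroms, k))
      else character(0)
      wgd <- runif(1) < 0.1
      tet <- simulateMeiosis(tinyParents, "father", errorSpec = spec,
                             wholeGenomeDiploidy = wgd)
      tot <- Reduce(`+`, lapply(tet, gameteCopies))
      expect_true(all(tot == 4L))
    }
  })
})

test_that("fertilization adds gamete contributions per chromosome", {
  sperm <- simulateGamete(fixParents, "father", seed = 41)
  eggDisomic <- simulateGamete(fixParents, "mother",
                               errorSpec = c("16" = "MI+"), seed = 42,
                               product = 1L)
  eggNull <- simulateGamete(fixParents, "mother",
                            errorSpec = c("16" = "MI-"), seed = 43,
                            product = 1L)
  tri <- formEmbryo(sperm, eggDisomic)
  expect_identical(totalCopies(tri)[["16"]], 3L)
  expect_identical(maternalCopies(tri)[["16"]], 2L)
  expect_identical(paternalCopies(tri)[["16"]], 1L)
  mono <- formEmbryo(sperm, eggNull)
  expect_identical(totalCopies(mono)[["16"]], 1L)
  expect_identical(maternalCopies(mono)[["16"]], 0L)

  # composition property: error-free gametes always give a euploid embryo
  for (s in 51:58) {
    emb <- formEmbryo(simulateGamete(fixParents, "father", seed = s),
                      simulateGamete(fixParents, "mother", seed = s + 100))
    expect_true(all(totalCopies(emb) == 2L))
    expect_true(all(maternalCopies(emb) == 1L))
  }
})

test_that("bin depth means track copy number and mosaic fraction", {
  sperm <- simulateGamete(fixParents, "father", seed = 61)
  egg <- simulateGamete(fixParents, "mother",
                        errorSpec = c("16" = "MI+"), seed = 62, product = 1L)
  emb <- formEmbryo(sperm, egg)
  flat <- binGenome(fixGenome, 1e4, flatGC = TRUE)
  prof <- simulateBinDepth(emb, flat, noiselessModel(), seed = 63)
  cnt <- bins(prof)$count
  chr <- as.character(GenomicRanges::seqnames(bins(prof)))
  basal <- mean(cnt[chr %in% c("1", "2")])
  # near-Poisson CV in the homogeneous noiseless limit
  cv <- sd(cnt[chr == "1"]) / mean(cnt[chr == "1"])
  expect_lt(abs(cv - 1 / sqrt(32)), 0.04)
  # trisomy 16: expected depth ratio 3/2
  expect_lt(abs(mean(cnt[chr == "16"]) / basal - 1.5), 0.05)

  # mosaic gain at f = 0.5: expected ratio (2 + 0.5)/2 = 1.25
  mosaic <- formEmbryo(simulateGamete(fixParents, "father", seed = 64),
                       simulateGamete(fixParents, "mother", seed = 65),
                       mosaicEvents = data.frame(
                         chrom = "15", start = 0,
                         end = fixGenome@seqlens[["15"]], delta = 1,
                         parent = "maternal", f = 0.5))
  mprof <- simulateBinDepth(mosaic, flat, noiselessModel(), seed = 66)
  mc <- bins(mprof)$count
  mchr <- as.character(GenomicRanges::seqnames(bins(mprof)))
  ratio <- mean(mc[mchr == "15"]) / mean(mc[mchr %in% c("1", "2")])
  expect_lt(abs(ratio - 1.25), 0.04)
})

test_that("allele counts reflect the embryo allele pool", {
  fatherGT <- genotypes(fixParents, "father")
  motherGT <- genotypes(fixParents, "mother")
  chr <- chromOf(fixPanel)
  aabb <- fatherGT == "AA" & motherGT == "BB"
  quiet <- noiselessModel()

  # disomic AABB locus: expected BAF 1/2
  emb <- formEmbryo(simulateGamete(fixParents, "father", seed = 71),
                    simulateGamete(fixParents, "mother", seed = 72))
  act <- simulateAlleleCounts(emb, fixParents, quiet, meanDepth = 200,
                              seed = 73)
  baf <- loci(act)$altCount / (loci(act)$refCount + loci(act)$altCount)
  expect_lt(abs(mean(baf[aabb]) - 0.5), 0.01)

  # maternal trisomy at AABB loci: pool A+B+B, expected BAF 2/3
  tri <- simulateAneuploidEmbryo(fixParents,
                                 data.frame(chrom = "16", parent = "maternal",
                                            type = "gain"), seed = 74)
  actTri <- simulateAlleleCounts(tri, fixParents, quiet, meanDepth = 200,
                                 seed = 75)
  bafT <- loci(actTri)$altCount /
    (loci(actTri)$refCount + loci(actTri)$altCount)
  sel <- aabb & chr == "16"
  expect_lt(abs(mean(bafT[sel]) - 2 / 3), 0.01)

  # paternal copy loss at AABB loci: only the maternal B remains
  mono <- simulateAneuploidEmbryo(fixParents,
                                  data.frame(chrom = "21", parent = "paternal",
                                             type = "loss"), seed = 76)
  actM <- simulateAlleleCounts(mono, fixParents, quiet, meanDepth = 50,
                               seed = 77)
  selM <- aabb & chr == "21"
  expect_true(all(loci(actM)$refCount[selM] == 0))
  expect_true(all(loci(actM)$altCount[selM] > 0))
})

test_that("whole-genome diploid gametes keep balanced heterozygosity", {
  wgd <- simulateGamete(fixParents, "father", wholeGenomeDiploidy = TRUE,
                        crossovers = 0L, seed = 81, product = 1L)
  expect_true(all(gameteCopies(wgd) == 2L))
  expect_true(wgd@diploid)
  hap <- slot(fixParents, "father")
  hetLoci <- rowSums(hap) == 1L
  chr <- chromOf(fixPanel)
  for (c2 in c("1", "16")) {
    A <- wgd@alleles[[c2]]
    expect_true(all((A[, 1] != A[, 2]) == hetLoci[chr == c2]))
  }
})

test_that("invalid simulation inputs fail loudly", {
  expect_error(simulateGamete(fixParents, "father",
                              errorSpec = c(ZZ = "MI")),
               "unknown chromosome")
  expect_error(simulateGamete(fixParents, "father",
                              errorSpec = c("16" = "trisomy")),
               "unknown error type")
  expect_error(formEmbryo(simulateGamete(fixParents, "father", seed = 1),
                          simulateGamete(simulateParents(flatPanel, seed = 2),
                                         "mother", seed = 3)),
               "share one SNP panel")
})
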