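test_that("informative marker selection keeps only discordant homozygotes", {
  mk <- function(f, m) {
    gr <- GenomicRanges::GRanges("1", IRanges::IRanges(
      start = seq_along(f) * 100, width = 1))
    gr$refCount <- rep(15L, length(f))
    gr$altCount <- rep(15L, length(f))
    gr$fatherGT <- f
    gr$motherGT <- m
    new("AlleleCountTable", loci = gr)
  }
  act <- mk(c("AA", "BB", "AB", "AA", "BB"),
            c("BB", "AA", "BB", "AA", "BB"))
  sel <- selectInformativeSnps(act, minInformative = 1L)
  expect_identical(sel$pattern, c("AABB", "BBAA"))
  expect_identical(sel$pos, c(100L, 200L))
  expect_true(all(sel$call == "AB"))
  small <- selectInformativeSnps(act, minInformative = 20L)
  expect_false(attr(small, "analyzable"))
})

test_that("genotype calls follow the BAF thresholds", {
  gr <- GenomicRanges::GRanges("1", IRanges::IRanges(
    start = (1:5) * 100, width = 1))
  gr$refCount <- c(30L, 0L, 15L, 5L, 30L)
  gr$altCount <- c(0L, 30L, 15L, 25L, 2L)   # baf 0, 1, .5, .833, .0625
  gr$fatherGT <- rep("AA", 5)
  gr$motherGT <- rep("BB", 5)
  act <- new("AlleleCountTable", loci = gr)
  sel <- selectInformativeSnps(act, minInformative = 1L)
  expect_identical(sel$call, c("AA", "BB", "AB", "no-call", "AA"))
})

test_that("the BAF Z statistic matches a direct arithmetic oracle", {
  mkMarkers <- function(baf, pattern) {
    data.frame(chrom = "1", pos = seq_along(baf), pattern = pattern,
               depth = 30, baf = baf, call = "AB")
  }
  regBaf <- rep(c(0.66, 0.68, 0.64, 0.70), 5)
  bgBafA <- rep(c(0.45, 0.55, 0.48, 0.52, 0.50), 8)
  bgBafB <- rep(c(0.44, 0.56, 0.47, 0.53, 0.50), 8)
  markers <- rbind(mkMarkers(regBaf, "AABB"),
                   mkMarkers(rev(1 - regBaf), "BBAA"))
  background <- rbind(mkMarkers(bgBafA, "AABB"), mkMarkers(bgBafB, "BBAA"))
  z <- bafZStatistic(markers, background)
  # independent arithmetic (sums and square roots only)
  oracle <- function(r, b) {
    mb <- sum(b) / length(b)
    sb <- sqrt(sum((b - mb)^2) / (length(b) - 1))
    (sum(r) / length(r) - mb) / (sb / sqrt(length(r)))
  }
  expect_equal(z$zAABB, oracle(regBaf, bgBafA), tolerance = 1e-12)
  expect_equal(z$zBBAA, oracle(1 - regBaf, bgBafB), tolerance = 1e-12)
  # identical distributions give Z = 0
  z0 <- bafZStatistic(mkMarkers(bgBafA, "AABB") |>
                        rbind(mkMarkers(bgBafB, "BBAA")), background)
  expect_equal(z0$zAABB, 0, tolerance = 1e-12)
  expect_equal(z0$zBBAA, 0, tolerance = 1e-12)
  # zero background variance is an error
  flat <- rbind(mkMarkers(rep(0.5, 60), "AABB"),
                mkMarkers(rep(0.5, 60), "BBAA"))
  expect_error(bafZStatistic(markers, flat), "zero BAF variance")
})

test_that("duplication and loss decision rules follow the printed thresholds", {
  mat <- duplicationOrigin(list(zAABB = 8, zBBAA = -7))
  expect_identical(mat$origin, "maternal")
  pat <- duplicationOrigin(list(zAABB = -8, zBBAA = 7))
  expect_identical(pat$origin, "paternal")
  expect_identical(duplicationOrigin(list(zAABB = 2, zBBAA = -1))$origin,
                   "undetermined")
  expect_identical(duplicationOrigin(list(zAABB = 8, zBBAA = 1))$origin,
                   "undetermined")  # no concurrent reversal
  expect_equal(duplicationOrigin(list(zAABB = 8, zBBAA = -7),
                                 extraCopies = 2)$expectedBaf, 0.75)

  mkLoss <- function(calls, pattern = "AABB") {
    data.frame(chrom = "1", pos = seq_along(calls), pattern = pattern,
               depth = 30, baf = 0.5, call = calls)
  }
  # 90% BB among AABB loci: the paternal A copy is gone
  lossP <- lossOrigin(mkLoss(c(rep("BB", 27), rep("AB", 3))))
  expect_identical(lossP$origin, "paternal")
  expect_equal(lossP$bbRatio, 0.9)
  lossM <- lossOrigin(mkLoss(c(rep("AA", 27), rep("AB", 3))))
  expect_identical(lossM$origin, "maternal")
  und <- lossOrigin(mkLoss(c(rep("AB", 15), rep("AA", 8), rep("BB", 7))))
  expect_identical(und$origin, "undetermined")
  expect_identical(lossOrigin(mkLoss(rep("BB", 10)))$origin, "undetermined")
})

test_that("origin recovery is perfect on noise-free embryos", {
  quiet <- noiselessModel()
  scenarios <- list(
    data.frame(chrom = "16", parent = "maternal", type = "gain"),
    data.frame(chrom = "2", parent = "paternal", type = "gain"),
    data.frame(chrom = "15", parent = "maternal", type = "loss"),
    data.frame(chrom = "21", parent = "paternal", type = "loss"),
    data.frame(chrom = c("1", "14", "16", "21"), parent = "maternal",
               type = "gain", stage = c("MI", "MII", "MI", "MII")))
  for (i in seq_along(scenarios)) {
    ev <- scenarios[[i]]
    truth <- simulateAneuploidEmbryo(fixParents, ev, seed = 100 + i)
    act <- simulateAlleleCounts(truth, fixParents, quiet, meanDepth = 40,
                                seed = 200 + i)
    calls <- data.frame(chrom = ev$chrom, event = ev$type)
    oc <- callOrigins(calls, act)
    expect_identical(nrow(oc), nrow(ev))
    expect_identical(oc$origin, ev$parent)
  }
  # euploid embryo: empty call list
  eu <- formEmbryo(simulateGamete(fixParents, "father", seed = 1),
                   simulateGamete(fixParents, "mother", seed = 2))
  actEu <- simulateAlleleCounts(eu, fixParents, quiet, seed = 3)
  ocEu <- callOrigins(data.frame(chrom = character(0), event = character(0)),
                      actEu)
  expect_identical(nrow(ocEu), 0L)
})

test_that("swapping parental labels swaps the Z pair and every call, exactly", {
  ev <- data.frame(chrom = c("16", "21"), parent = c("maternal", "paternal"),
                   type = c("gain", "loss"))
  truth <- simulateAneuploidEmbryo(fixParents, ev, seed = 301)
  act <- simulateAlleleCounts(truth, fixParents, noiseModel(), seed = 302)
  calls <- data.frame(chrom = ev$chrom, event = ev$type)
  oc <- callOrigins(calls, act)
  ocSwap <- callOrigins(calls, swapParentsInTable(act))
  expect_identical(ocSwap$zAABB, oc$zBBAA)
  expect_identical(ocSwap$zBBAA, oc$zAABB)
  expect_identical(ocSwap$aaRatio, oc$bbRatio)
  expect_identical(ocSwap$bbRatio, oc$aaRatio)
  flip <- c(maternal = "paternal", paternal = "maternal",
            undetermined = "undetermined")
  expect_identical(ocSwap$origin, unname(flip[oc$origin]))
})

test_that("raising allele dropout never raises the determined-call rate", {
  determinedRate <- function(dropout, nRep = 24) {
    hits <- vapply(seq_len(nRep), function(r) {
      ev <- data.frame(chrom = "16", parent = "maternal", type = "gain")
      truth <- simulateAneuploidEmbryo(fixParents, ev, seed = 4000 + r)
      act <- simulateAlleleCounts(
        truth, fixParents, noiseModel(dropout = dropout), meanDepth = 20,
        seed = 5000 + r)
      oc <- callOrigins(data.frame(chrom = "16", event = "gain"), act)
      oc$origin[1] != "undetermined"
    }, logical(1))
    mean(hits)
  }
  expect_gte(determinedRate(0), determinedRate(0.45))
})
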