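#' Simulate parental genotypes under Hardy-Weinberg equilibrium
#'
#' Each parent receives two haplotypes per locus, with the B allele drawn
#' independently at the locus's population frequency. Haplotypes are kept so
#' meiosis can transmit recombinant chromatids.
#'
#' @param panel a [SnpPanel-class].
#' @param seed RNG seed.
#' @return a [ParentalGenotypes-class].
#' @examples
#' gm <- genomeModel(c("1", "2"))
#' parents <- simulateParents(snpPanel(gm, 200, seed = 1), seed = 2)
#' @export
simulateParents <- function(panel, seed = NULL) {
  stopifnot(is(panel, "SnpPanel"))
  n <- length(panel@loci)
  if (n == 0L) stop("empty SNP panel")
  p <- panel@loci$popBaf
  withSeed(seed, {
    draw <- function() matrix(rbinom(2L * n, 1L, rep(p, 2L)), ncol = 2L)
    new("ParentalGenotypes", panel = panel, father = draw(), mother = draw())
  })
}

.ERROR_TYPES <- c("MI", "MI+", "MI-", "MII", "MII+", "MII-")

# One meiosis for one parent side; returns the four products as lists of
# chromatid matrices. Chromatid columns 1,2 are sisters of homolog 1 and
# 3,4 of homolog 2; a single crossover swaps the segment distal to the
# exchange point on the arm where it falls, so the centromere-proximal
# signature (MI disomy heterozygous, MII disomy homozygous) is preserved.
.meiosis <- function(panel, hap, errorSpec, wholeGenomeDiploidy, crossovers) {
  genome <- panel@genome
  chroms <- names(genome@seqlens)
  idx <- .lociByChrom(panel)
  pos <- start(panel@loci)
  products <- replicate(4L, vector("list", length(chroms)), simplify = FALSE)
  errAnn <- matrix("none", nrow = length(chroms), ncol = 4L,
                   dimnames = list(chroms, NULL))
  for (ci in seq_along(chroms)) {
    chr <- chroms[ci]
    rows <- idx[[chr]]
    chromatids <- hap[rows, c(1L, 1L, 2L, 2L), drop = FALSE]
    len <- genome@seqlens[[chr]]
    cen <- genome@centromeres[[chr]]
    p <- pos[rows]
    nxo <- crossovers
    for (k in seq_len(nxo)) {
      u <- runif(1, 0, len)
      i <- sample(1:2, 1L)
      j <- sample(3:4, 1L)
      sel <- if (u >= cen) p > u else p <= u
      if (any(sel)) {
        tmp <- chromatids[sel, i]
        chromatids[sel, i] <- chromatids[sel, j]
        chromatids[sel, j] <- tmp
      }
    }
    if (wholeGenomeDiploidy) {
      assign4 <- list(c(1L, 3L), c(2L, 4L), integer(0), integer(0))
      errAnn[ci, ] <- "whole-genome-diploidy"
    } else {
      err <- if (chr %in% names(errorSpec)) errorSpec[[chr]] else "none"
      if (err == "none") {
        assign4 <- list(1L, 2L, 3L, 4L)
      } else {
        kind <- sub("[+-]$", "", err)
        orient <- sub("^MI{1,2}", "", err)
        if (orient == "") orient <- sample(c("+", "-"), 1L)
        if (kind == "MI") {
          assign4 <- if (orient == "+")
            list(c(1L, 3L), c(2L, 4L), integer(0), integer(0))
          else list(integer(0), integer(0), c(1L, 3L), c(2L, 4L))
          errAnn[ci, lengths(assign4) != 1L] <- "MI-nondisjunction"
        } else {
          assign4 <- if (orient == "+")
            list(c(1L, 2L), integer(0), 3L, 4L)
          else list(integer(0), c(1L, 2L), 3L, 4L)
          errAnn[ci, lengths(assign4) != 1L] <- "MII-nondisjunction"
        }
      }
    }
    for (pr in 1:4)
      products[[pr]][[ci]] <- chromatids[, assign4[[pr]], drop = FALSE]
  }
  for (pr in 1:4) names(products[[pr]]) <- chroms
  list(products = products, errors = errAnn)
}

.gameteFromProduct <- function(panel, alleles, errors, diploid) {
  copies <- vapply(alleles, ncol, integer(1))
  new("GameteKaryotype", panel = panel, copies = copies, alleles = alleles,
      errors = errors, diploid = diploid)
}

.checkErrorSpec <- function(errorSpec, genome) {
  if (!length(errorSpec)) return(invisible())
  bad <- setdiff(names(errorSpec), names(genome@seqlens))
  if (length(bad)) stop("unknown chromosome id in errorSpec: ",
                        paste(bad, collapse = ", "))
  badv <- setdiff(errorSpec, .ERROR_TYPES)
  if (length(badv)) stop("unknown error type: ", paste(badv, collapse = ", "),
                         " (use MI/MII, optionally with +/- orientation)")
  invisible()
}

#' Simulate one complete meiosis (all four products)
#'
#' Runs one meiosis for the given parent and returns the full tetrad, so that
#' conservation (four copies of every chromosome across the four products)
#' can be checked directly. Chromosomes without error transmit one
#' recombinant chromatid per product. An MI nondisjunction sends both
#' homologs to one pole: two products receive one chromatid of each homolog
#' (heterozygosity preserved at centromere-proximal loci) and two receive
#' none. An MII nondisjunction keeps two sister chromatids together: one
#' product receives both sisters (homozygous centromere-proximally), one
#' receives none, and the other two are normal. Whole-genome diploidy models
#' an unreduced gamete: two products carry one chromatid of each homolog for
#' every chromosome (balanced heterozygosity), two are empty.
#'
#' @param parents a [ParentalGenotypes-class].
#' @param side `"father"` or `"mother"`.
#' @param errorSpec named character vector, chromosome -> error type in
#'   `c("MI","MII")`, optionally suffixed `+`/`-` to force product 1 to be
#'   the disomic (`+`) or nullisomic (`-`) one; bare types randomize the
#'   pole.
#' @param wholeGenomeDiploidy simulate an unreduced meiosis.
#' @param crossovers crossovers per chromosome (default 1, positions
#'   uniform).
#' @param seed RNG seed.
#' @return list of four [GameteKaryotype-class] objects.
#' @export
simulateMeiosis <- function(parents, side = c("father", "mother"),
                            errorSpec = character(0),
                            wholeGenomeDiploidy = FALSE,
                            crossovers = 1L, seed = NULL) {
  stopifnot(is(parents, "ParentalGenotypes"))
  side <- match.arg(side)
  panel <- parents@panel
  .checkErrorSpec(errorSpec, panel@genome)
  withSeed(seed, {
    m <- .meiosis(panel, slot(parents, side), errorSpec,
                  wholeGenomeDiploidy, crossovers)
    lapply(1:4, function(pr) {
      errs <- m$errors[, pr]
      dip <- wholeGenomeDiploidy &&
        all(vapply(m$products[[pr]], ncol, integer(1)) == 2L)
      .gameteFromProduct(panel, m$products[[pr]], errs, dip)
    })
  })
}

#' Simulate a single gamete
#'
#' Convenience wrapper around [simulateMeiosis()] returning one product.
#'
#' @inheritParams simulateMeiosis
#' @param product which meiotic product to transmit (1-4); `NULL` picks one
#'   uniformly at random. With orientation suffix `+` in `errorSpec`,
#'   product 1 is guaranteed disomic for that chromosome.
#' @return a [GameteKaryotype-class].
#' @examples
#' gm <- genomeModel(c("16", "21"))
#' parents <- simulateParents(snpPanel(gm, 100, seed = 1), seed = 1)
#' g <- simulateGamete(parents, "mother", errorSpec = c("21" = "MI+"),
#'                     product = 1, seed = 7)
#' gameteCopies(g)[["21"]] # 2
#' @export
simulateGamete <- function(parents, side = c("father", "mother"),
                           errorSpec = character(0),
                           wholeGenomeDiploidy = FALSE, crossovers = 1L,
                           seed = NULL, product = NULL) {
  side <- match.arg(side)
  stopifnot(is(parents, "ParentalGenotypes"))
  .checkErrorSpec(errorSpec, parents@panel@genome)
  withSeed(seed, {
    m <- .meiosis(parents@panel, slot(parents, side), errorSpec,
                  wholeGenomeDiploidy, crossovers)
    pr <- if (is.null(product)) sample(4L, 1L) else as.integer(product)
    stopifnot(pr %in% 1:4)
    errs <- m$errors[, pr]
    dip <- wholeGenomeDiploidy &&
      all(vapply(m$products[[pr]], ncol, integer(1)) == 2L)
    .gameteFromProduct(parents@panel, m$products[[pr]], errs, dip)
  })
}

#' Fertilize: combine two gametes into ground-truth embryo karyotype
#'
#' Per-chromosome maternal/paternal copy numbers are the sums of the gamete
#' contributions. Optional mosaic/segmental events are appended with their
#' abnormal-cell fraction `f` (`f = 1` marks a constitutive event); they
#' modulate the sequencing observables but not the constitutive copy
#' decomposition.
#'
#' @param sperm,egg [GameteKaryotype-class] objects on the same panel.
#' @param mosaicEvents optional data.frame with columns
#'   `chrom,start,end,delta,parent,f` (half-open bp intervals; `delta` is
#'   the signed copy change; `parent` is `"maternal"`/`"paternal"`).
#' @return an [EmbryoTruth-class].
#' @examples
#' gm <- genomeModel(c("16", "21"))
#' parents <- simulateParents(snpPanel(gm, 100, seed = 1), seed = 1)
#' sperm <- simulateGamete(parents, "father", seed = 2)
#' egg <- simulateGamete(parents, "mother", seed = 3)
#' formEmbryo(sperm, egg) # euploid
#' @export
formEmbryo <- function(sperm, egg, mosaicEvents = NULL) {
  stopifnot(is(sperm, "GameteKaryotype"), is(egg, "GameteKaryotype"))
  if (!identical(granges(sperm@panel@loci), granges(egg@panel@loci)))
    stop("gametes must share one SNP panel")
  panel <- egg@panel
  chroms <- names(panel@genome@seqlens)
  alleles <- vector("list", length(chroms)); names(alleles) <- chroms
  parentOf <- vector("list", length(chroms)); names(parentOf) <- chroms
  for (chr in chroms) {
    alleles[[chr]] <- cbind(egg@alleles[[chr]], sperm@alleles[[chr]])
    parentOf[[chr]] <- c(rep("maternal", ncol(egg@alleles[[chr]])),
                         rep("paternal", ncol(sperm@alleles[[chr]])))
  }
  ev <- if (is.null(mosaicEvents))
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               delta = numeric(0), parent = character(0), f = numeric(0))
  else as.data.frame(mosaicEvents)
  if (nrow(ev)) {
    ev$chrom <- as.character(ev$chrom)
    stopifnot(all(ev$parent %in% c("maternal", "paternal")))
    for (r in seq_len(nrow(ev))) {
      if (ev$delta[r] < 0 &&
          sum(parentOf[[ev$chrom[r]]] == ev$parent[r]) == 0L)
        stop("copy-loss event on a chromosome with no ", ev$parent[r], " copy")
    }
  }
  new("EmbryoTruth", panel = panel,
      maternalCopies = egg@copies, paternalCopies = sperm@copies,
      alleles = alleles, parentOf = parentOf, events = ev)
}

# effective copy number per bin given constitutive copies and mosaic events
.binCopyNumber <- function(truthLike, binsGr) {
  chroms <- as.character(seqnames(binsGr))
  if (is(truthLike, "GameteKaryotype")) {
    cn <- as.numeric(truthLike@copies[chroms])
    ev <- NULL
  } else {
    tot <- truthLike@maternalCopies + truthLike@paternalCopies
    cn <- as.numeric(tot[chroms])
    ev <- truthLike@events
  }
  if (!is.null(ev) && nrow(ev)) {
    for (r in seq_len(nrow(ev))) {
      hit <- which(chroms == ev$chrom[r] &
                   (start(binsGr) - 1L) < ev$end[r] &
                   end(binsGr) > ev$start[r])
      cn[hit] <- cn[hit] + ev$f[r] * ev$delta[r]
    }
  }
  pmax(cn, 0)
}

#' Simulate binned read depth for a cell or embryo
#'
#' Bin counts are negative-binomial with mean proportional to the local copy
#' number times a monotone GC efficiency; mosaic events contribute
#' `f * delta` extra mean. The mean is absolute (reads scale with DNA
#' content), so an unreduced diploid cell yields about twice the reads of a
#' haploid one.
#'
#' @param truth an [EmbryoTruth-class] or [GameteKaryotype-class].
#' @param binsGr bins from [binGenome()] (10-kb for embryos, 20-kb for
#'   sperm).
#' @param noise a [NoiseModel-class].
#' @param seed RNG seed.
#' @return a [BinnedDepthProfile-class] (baseline `"diploid"` for embryos,
#'   `"haploid"` for gametes).
#' @export
simulateBinDepth <- function(truth, binsGr, noise = noiseModel(), seed = NULL) {
  stopifnot(is(noise, "NoiseModel"), is(binsGr, "GRanges"))
  isEmbryo <- is(truth, "EmbryoTruth")
  if (!isEmbryo && !is(truth, "GameteKaryotype"))
    stop("truth must be an EmbryoTruth or GameteKaryotype")
  basePloidy <- if (isEmbryo) 2 else 1
  cn <- .binCopyNumber(truth, binsGr)
  eff <- exp(noise@gcSlope * (binsGr$gc - 0.45))
  eff <- eff / mean(eff)
  mu <- noise@meanReadsPerBin * (cn / basePloidy) * eff
  counts <- withSeed(seed,
    rnbinom(length(mu), size = noise@dispersion, mu = mu))
  gr <- granges(binsGr)
  gr$gc <- binsGr$gc
  gr$count <- as.numeric(counts)
  new("BinnedDepthProfile", bins = gr,
      baseline = if (isEmbryo) "diploid" else "haploid", normalized = FALSE)
}

#' Simulate SNP-level allele counts with allele dropout
#'
#' Reads at each panel locus are drawn from the cell's allele pool: every
#' constitutive copy contributes weight 1, and each mosaic event adds
#' (gain) or removes (loss) weight `f` from a copy of the stated parent.
#' MDA-style allele dropout removes each copy independently with the model's
#' dropout probability, and each read reports the opposite allele with the
#' sequencing-error probability. Loci whose entire pool drops out get zero
#' depth.
#'
#' @param truth an [EmbryoTruth-class] or [GameteKaryotype-class].
#' @param parents the [ParentalGenotypes-class] (for the reported parental
#'   genotype columns).
#' @param noise a [NoiseModel-class].
#' @param meanDepth mean reads per locus (Poisson).
#' @param seed RNG seed.
#' @return an [AlleleCountTable-class].
#' @export
simulateAlleleCounts <- function(truth, parents, noise = noiseModel(),
                                 meanDepth = 30, seed = NULL) {
  stopifnot(is(parents, "ParentalGenotypes"), meanDepth > 0)
  isEmbryo <- is(truth, "EmbryoTruth")
  if (!isEmbryo && !is(truth, "GameteKaryotype"))
    stop("truth must be an EmbryoTruth or GameteKaryotype")
  panel <- parents@panel
  idx <- .lociByChrom(panel)
  pos <- start(panel@loci)
  n <- length(panel@loci)
  pB <- rep(NA_real_, n)
  withSeed(seed, {
    for (chr in names(idx)) {
      rows <- idx[[chr]]
      A <- truth@alleles[[chr]]
      if (is.null(A)) next
      C <- ncol(A)
      if (C == 0L) { pB[rows] <- NA_real_; next }
      W <- matrix(1, nrow = length(rows), ncol = C)
      if (isEmbryo) {
        po <- truth@parentOf[[chr]]
        ev <- truth@events
        ev <- ev[ev$chrom == chr, , drop = FALSE]
        for (r in seq_len(nrow(ev))) {
          inEv <- pos[rows] > ev$start[r] & pos[rows] <= ev$end[r]
          if (!any(inEv)) next
          k <- abs(ev$delta[r])
          cand <- which(po == ev$parent[r])
          if (ev$delta[r] > 0) {
            src <- if (length(cand)) cand[1L] else 1L
            for (j in seq_len(k)) {
              A <- cbind(A, A[, src])
              w <- numeric(length(rows)); w[inEv] <- ev$f[r]
              W <- cbind(W, w)
            }
          } else {
            for (j in seq_len(min(k, length(cand))))
              W[inEv, cand[j]] <- pmax(W[inEv, cand[j]] - ev$f[r], 0)
          }
        }
      }
      if (noise@dropout > 0) {
        keep <- matrix(runif(length(W)) >= noise@dropout,
                       nrow = nrow(W))
        W <- W * keep
      }
      tw <- rowSums(W)
      pb <- ifelse(tw > 0, rowSums(W * A) / tw, NA_real_)
      pB[rows] <- pb
    }
    depth <- rpois(n, meanDepth)
    depth[is.na(pB)] <- 0L
    e <- noise@seqError
    pRead <- ifelse(is.na(pB), 0, pB * (1 - e) + (1 - pB) * e)
    alt <- rbinom(n, depth, pRead)
    gr <- granges(panel@loci)
    gr$refCount <- as.integer(depth - alt)
    gr$altCount <- as.integer(alt)
    gr$fatherGT <- genotypes(parents, "father")
    gr$motherGT <- genotypes(parents, "mother")
    new("AlleleCountTable", loci = gr)
  })
}
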