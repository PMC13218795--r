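#' Select informative SNP markers for parental-origin analysis
#'
#' Informative loci are those where the two parents are homozygous for
#' opposite alleles: pattern `"AABB"` (father AA, mother BB) or the
#' reciprocal `"BBAA"` (father BB, mother AA). At such loci every read
#' allele is assignable to a parent without phasing. Embryo genotypes are
#' called from the B-allele read fraction: AA below `aaMax`, AB inside
#' `[abMin, abMax]`, BB above `bbMin`, otherwise no-call; loci below
#' `minDepth` are no-calls.
#'
#' @param alleleCounts an [AlleleCountTable-class] (carries the parental
#'   genotypes).
#' @param region `NULL` for genome-wide, a chromosome id, or a `GRanges`
#'   interval.
#' @param minInformative minimum informative loci for the region to be
#'   analyzable (attribute `"analyzable"` on the result).
#' @param minDepth minimum reads per locus for a genotype call.
#' @param aaMax,abMin,abMax,bbMin genotype-call BAF thresholds.
#' @return data.frame with columns `chrom,pos,pattern,depth,baf,call` and
#'   attribute `"analyzable"`.
#' @export
selectInformativeSnps <- function(alleleCounts, region = NULL,
                                  minInformative = 20L, minDepth = 10L,
                                  aaMax = 0.1, abMin = 0.2, abMax = 0.8,
                                  bbMin = 0.9) {
  stopifnot(is(alleleCounts, "AlleleCountTable"))
  gr <- alleleCounts@loci
  pattern <- ifelse(gr$fatherGT == "AA" & gr$motherGT == "BB", "AABB",
                    ifelse(gr$fatherGT == "BB" & gr$motherGT == "AA", "BBAA",
                           NA_character_))
  keep <- !is.na(pattern)
  if (!is.null(region)) {
    inRegion <- if (is(region, "GRanges")) {
      overlapsAny <- rep(FALSE, length(gr))
      ov <- findOverlaps(gr, region)
      overlapsAny[queryHits(ov)] <- TRUE
      overlapsAny
    } else as.character(seqnames(gr)) %in% as.character(region)
    keep <- keep & inRegion
  }
  idx <- which(keep)
  depth <- gr$refCount[idx] + gr$altCount[idx]
  baf <- ifelse(depth > 0, gr$altCount[idx] / depth, NA_real_)
  call <- ifelse(depth < minDepth | is.na(baf), "no-call",
                 ifelse(baf < aaMax, "AA",
                        ifelse(baf > bbMin, "BB",
                               ifelse(baf >= abMin & baf <= abMax, "AB",
                                      "no-call"))))
  out <- data.frame(chrom = as.character(seqnames(gr))[idx],
                    pos = start(gr)[idx], pattern = pattern[idx],
                    depth = depth, baf = baf, call = call)
  rownames(out) <- NULL
  attr(out, "analyzable") <- nrow(out) >= minInformative
  out
}

#' B-allele-frequency Z statistic for a candidate CNV region
#'
#' Compares mean BAF at AB-genotype informative loci inside the region with
#' the mean over AB loci in copy-number-neutral regions (theoretical BAF
#' 0.5 in diploid regions), separately for the AABB and BBAA patterns:
#' `Z = (mean_region - mean_background) / (sd_background / sqrt(n_region))`.
#' An extra maternal copy pushes AABB-locus BAF toward 2/3 (Z positive) and
#' BBAA-locus BAF toward 1/3 (Z negative); a paternal gain reverses both
#' signs.
#'
#' @param markers informative-marker table for the region (from
#'   [selectInformativeSnps()]).
#' @param background informative-marker table for CNV-free regions.
#' @param minAB minimum AB-genotype loci per pattern inside the region
#'   (below it the pattern's Z is NA).
#' @param minBackground minimum AB-genotype background loci (both patterns
#'   combined).
#' @return list with `zAABB`, `zBBAA`, regional and background means, and
#'   per-pattern AB-locus counts.
#' @export
bafZStatistic <- function(markers, background, minAB = 10L,
                          minBackground = 50L) {
  regAB <- markers[markers$call == "AB", , drop = FALSE]
  bgAB <- background[background$call == "AB", , drop = FALSE]
  if (nrow(bgAB) < minBackground)
    stop("need at least ", minBackground, " AB background loci")
  one <- function(pat) {
    rb <- regAB$baf[regAB$pattern == pat]
    bb <- bgAB$baf[bgAB$pattern == pat]
    if (length(bb) < 2L) stop("too few background loci for pattern ", pat)
    s <- sd(bb)
    if (s == 0) stop("zero BAF variance outside CNV regions")
    n <- length(rb)
    z <- if (n < minAB) NA_real_ else (mean(rb) - mean(bb)) / (s / sqrt(n))
    list(z = z, mean = if (n) mean(rb) else NA_real_, bgMean = mean(bb),
         n = n)
  }
  a <- one("AABB"); b <- one("BBAA")
  list(zAABB = a$z, zBBAA = b$z, meanAABB = a$mean, meanBBAA = b$mean,
       bgMeanAABB = a$bgMean, bgMeanBBAA = b$bgMean,
       nAABB = a$n, nBBAA = b$n)
}

#' Parental origin of a duplication from the pattern Z statistics
#'
#' Maternal duplication: AABB-pattern AB-locus BAF above 0.5 with the BBAA
#' pattern concurrently below 0.5 (Z above +`zThreshold` and below
#' -`zThreshold` respectively); paternal duplication shows the reversed
#' trends. Anything else is undetermined. For a gain of `k` extra copies
#' the expected informative-locus BAF is `(1+k)/(2+k)` (reported, not
#' thresholded).
#'
#' @param z result of [bafZStatistic()].
#' @param zThreshold significance threshold on |Z| (default 3).
#' @param extraCopies assumed number of extra copies `k` (for the reported
#'   expected BAF only).
#' @return list with `origin` (maternal/paternal/undetermined), the Z pair,
#'   and `expectedBaf`.
#' @export
duplicationOrigin <- function(z, zThreshold = 3, extraCopies = 1) {
  za <- z$zAABB; zb <- z$zBBAA
  origin <- if (!is.na(za) && !is.na(zb) && za > zThreshold && zb < -zThreshold)
    "maternal"
  else if (!is.na(za) && !is.na(zb) && za < -zThreshold && zb > zThreshold)
    "paternal"
  else "undetermined"
  list(origin = origin, zAABB = za, zBBAA = zb,
       expectedBaf = (1 + extraCopies) / (2 + extraCopies))
}

#' Parental origin of a copy loss from genotype ratios
#'
#' Among AABB-pattern loci in the lost region, losing the paternal copy
#' leaves only the maternal B allele (loci called BB), and losing the
#' maternal copy leaves only the paternal A (loci called AA). Paternal loss
#' is called when the BB fraction exceeds `ratioThreshold`, maternal loss
#' when the AA fraction does; the reciprocal BBAA loci are evaluated
#' symmetrically as an advisory consistency check (not blocking).
#'
#' @param markers informative-marker table for the lost region.
#' @param ratioThreshold genotype-ratio threshold (default 0.8).
#' @param minLoci minimum called AABB loci required for a determination.
#' @return list with `origin`, `aaRatio`, `bbRatio`, `nLoci`, and
#'   `reciprocalConsistent` (logical or NA).
#' @export
lossOrigin <- function(markers, ratioThreshold = 0.8, minLoci = 20L) {
  called <- markers[markers$call %in% c("AA", "AB", "BB"), , drop = FALSE]
  ab <- called[called$pattern == "AABB", , drop = FALSE]
  n <- nrow(ab)
  aaRatio <- if (n) mean(ab$call == "AA") else NA_real_
  bbRatio <- if (n) mean(ab$call == "BB") else NA_real_
  origin <- if (n < minLoci) "undetermined"
  else if (bbRatio > ratioThreshold) "paternal"
  else if (aaRatio > ratioThreshold) "maternal"
  else "undetermined"
  ba <- called[called$pattern == "BBAA", , drop = FALSE]
  reciprocal <- NA
  if (nrow(ba) >= 5L && origin != "undetermined") {
    # paternal loss leaves maternal A at BBAA loci, i.e. AA calls
    expect <- if (origin == "paternal") "AA" else "BB"
    reciprocal <- mean(ba$call == expect) > ratioThreshold
  }
  list(origin = origin, aaRatio = aaRatio, bbRatio = bbRatio, nLoci = n,
       reciprocalConsistent = reciprocal)
}

#' Assign parental origin to every whole-chromosome aneuploidy of an embryo
#'
#' Gains go through the BAF Z-test path ([bafZStatistic()] +
#' [duplicationOrigin()]), losses through the genotype-ratio path
#' ([lossOrigin()]). Background loci are taken from chromosomes with no
#' copy-number event.
#'
#' @param cnv a [CopyNumberProfile-class] with chromosome calls populated,
#'   or a data.frame with columns `chrom` and `event` (`"gain"`/`"loss"`).
#' @param alleleCounts the embryo's [AlleleCountTable-class] (with parental
#'   genotypes; error if absent).
#' @param zThreshold,ratioThreshold,minInformative,minAB decision
#'   parameters passed through to the per-region rules.
#' @return data.frame with one row per aneuploid whole-chromosome event
#'   (`region,event,origin,zAABB,zBBAA,aaRatio,bbRatio,nLoci`) and
#'   attribute `"summary"` (named maternal/paternal/undetermined counts).
#'   Euploid embryos yield a zero-row table.
#' @export
callOrigins <- function(cnv, alleleCounts, zThreshold = 3,
                        ratioThreshold = 0.8, minInformative = 20L,
                        minAB = 10L) {
  if (is(cnv, "CopyNumberProfile")) {
    cc <- cnv@chromCalls
    if (is.null(cc)) stop("chromosome calls must be populated first")
    events <- cc[cc$event %in% c("gain", "loss") &
                   cc$status %in% "aneuploid", c("chrom", "event")]
    quiet <- cc$chrom[cc$event == "none"]
  } else {
    events <- as.data.frame(cnv)[, c("chrom", "event")]
    stopifnot(all(events$event %in% c("gain", "loss")))
    allChr <- unique(as.character(seqnames(alleleCounts@loci)))
    quiet <- setdiff(allChr, events$chrom)
  }
  if (!is(alleleCounts, "AlleleCountTable"))
    stop("missing parental genotypes: alleleCounts must be an AlleleCountTable")
  events$chrom <- as.character(events$chrom)
  background <- selectInformativeSnps(alleleCounts, region = quiet,
                                      minInformative = 1L)
  rows <- lapply(seq_len(nrow(events)), function(i) {
    chr <- events$chrom[i]
    ev <- events$event[i]
    mk <- selectInformativeSnps(alleleCounts, region = chr,
                                minInformative = minInformative)
    row <- data.frame(region = chr, event = if (ev == "gain") "duplication"
                      else "loss",
                      origin = "undetermined", zAABB = NA_real_,
                      zBBAA = NA_real_, aaRatio = NA_real_,
                      bbRatio = NA_real_, nLoci = nrow(mk))
    if (!attr(mk, "analyzable")) return(row)
    if (ev == "gain") {
      z <- tryCatch(bafZStatistic(mk, background, minAB = minAB),
                    error = function(e) NULL)
      if (is.null(z)) return(row)
      d <- duplicationOrigin(z, zThreshold = zThreshold)
      row$origin <- d$origin
      row$zAABB <- z$zAABB; row$zBBAA <- z$zBBAA
    } else {
      l <- lossOrigin(mk, ratioThreshold = ratioThreshold,
                      minLoci = min(minInformative, 20L))
      row$origin <- l$origin
      row$aaRatio <- l$aaRatio; row$bbRatio <- l$bbRatio
      row$nLoci <- l$nLoci
    }
    row
  })
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(region = character(0), event = character(0),
                  origin = character(0), zAABB = numeric(0),
                  zBBAA = numeric(0), aaRatio = numeric(0),
                  bbRatio = numeric(0), nLoci = integer(0))
  rownames(out) <- NULL
  attr(out, "summary") <- c(
    maternal = sum(out$origin == "maternal"),
    paternal = sum(out$origin == "paternal"),
    undetermined = sum(out$origin == "undetermined"))
  out
}
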