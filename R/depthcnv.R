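#' GC-normalize a binned depth profile
#'
#' Fits a locally weighted regression of count on GC fraction (robust
#' `lowess`, span 0.3 by default) over well-behaved bins (GC inside
#' `gcRange`, non-zero count), divides counts by the fit, and rescales so the
#' genome-wide median count is preserved. With constant GC the operation
#' degenerates to a pure rescaling.
#'
#' @param profile a [BinnedDepthProfile-class] with at least 200 bins.
#' @param span lowess span.
#' @param gcRange bins with GC outside this range are masked from the fit.
#' @return the normalized [BinnedDepthProfile-class].
#' @export
gcNormalize <- function(profile, span = 0.3, gcRange = c(0.3, 0.6)) {
  stopifnot(is(profile, "BinnedDepthProfile"))
  gr <- profile@bins
  if (length(gr) < 200L) stop("need at least 200 bins to fit the GC curve")
  count <- gr$count
  if (all(count == 0)) stop("all-zero counts: nothing to normalize")
  gc <- gr$gc
  mask <- gc >= gcRange[1] & gc <= gcRange[2] & count > 0
  if (sum(mask) < 50L) stop("too few usable bins inside the GC range")
  if (diff(range(gc[mask])) < 1e-8) {
    fitted <- rep(mean(count[mask]), length(gr))
  } else {
    lw <- lowess(gc[mask], count[mask], f = span, iter = 3L)
    fitted <- approx(lw$x, lw$y, xout = gc, rule = 2, ties = mean)$y
  }
  floorVal <- max(1e-8, 0.05 * median(count[mask]))
  fitted <- pmax(fitted, floorVal)
  norm <- count / fitted
  scaleTo <- median(count[count > 0])
  norm <- norm * scaleTo / median(norm[count > 0])
  gr$count <- norm
  new("BinnedDepthProfile", bins = gr, baseline = profile@baseline,
      normalized = TRUE)
}

#' Compute baseline-relative copy ratios
#'
#' Per-bin ratio = baseline copies x normalized count / reference level, with
#' baseline 2 for embryos (diploid) and 1 for sperm (haploid). The reference
#' is either a bin-matched normalized control profile (required to see
#' genome-wide ploidy shifts such as a fully diploid sperm) or, by default,
#' the profile's own median level (which washes out uniform ploidy -- that is
#' exactly why sperm ploidy additionally integrates the heterozygosity
#' index).
#'
#' @param profile a normalized [BinnedDepthProfile-class].
#' @param reference optional bin-matched normalized
#'   [BinnedDepthProfile-class] control; `NULL` uses the self-median.
#' @return a [CopyNumberProfile-class] with ratios populated and calls empty.
#' @export
copyRatioProfile <- function(profile, reference = NULL) {
  stopifnot(is(profile, "BinnedDepthProfile"))
  if (!profile@normalized) stop("profile must be GC-normalized first")
  base <- if (profile@baseline == "diploid") 2 else 1
  gr <- profile@bins
  if (is.null(reference)) {
    level <- median(gr$count[gr$count > 0])
    ratio <- base * gr$count / level
  } else {
    stopifnot(is(reference, "BinnedDepthProfile"))
    if (!reference@normalized) stop("reference must be GC-normalized")
    if (!identical(granges(gr), granges(reference@bins)))
      stop("reference bin mismatch")
    ref <- reference@bins$count
    ratio <- ifelse(ref > 0, base * gr$count / ref, NA_real_)
  }
  gr$ratio <- ratio
  new("CopyNumberProfile", bins = gr, baseline = base,
      chromCalls = NULL, segCalls = NULL)
}

# euploid / mosaic / aneuploid by the 30%/70% abnormal-cell-fraction rule
.statusFromF <- function(f) {
  ifelse(is.na(f), NA_character_,
         ifelse(f < 0.30, "euploid",
                ifelse(f <= 0.70, "mosaic", "aneuploid")))
}

#' Call whole-chromosome copy-number events
#'
#' For each chromosome the abnormal-cell fraction is estimated as
#' `f = |median ratio - baseline|` (single-copy delta assumed), clipped to
#' \[0,1\] and rounded to 10 decimals so that threshold comparisons at the
#' 0.30/0.70 boundaries behave exactly. Status follows the cell-fraction
#' rule: euploid below 30%, mosaic between 30% and 70% inclusive, aneuploid
#' above 70%. A whole-chromosome call additionally requires at least
#' `consistency` of the chromosome's bins to deviate in the call direction;
#' otherwise the candidate is delegated to segmental calling. Ratios at or
#' above `multiCopyRatio` (multi-copy gains) are reported with an integer
#' copy estimate and `f = 1`. Chromosomes with fewer than `minBins` bins are
#' returned as `"no-call"` with a warning.
#'
#' @param cn a [CopyNumberProfile-class] with ratios computed.
#' @param minBins minimum bins per chromosome.
#' @param consistency minimum fraction of bins deviating in the call
#'   direction for a whole-chromosome call.
#' @param euploidMax abnormal-cell-fraction below which a chromosome is
#'   euploid (0.30).
#' @param multiCopyRatio ratio (diploid baseline scale) at or above which a
#'   gain is treated as multi-copy; scaled by baseline/2 internally.
#' @return the profile with `chromCalls` populated.
#' @export
callChromosomeCNVs <- function(cn, minBins = 10L, consistency = 0.8,
                               euploidMax = 0.30, multiCopyRatio = 3.5) {
  stopifnot(is(cn, "CopyNumberProfile"))
  gr <- cn@bins
  base <- cn@baseline
  multiCut <- multiCopyRatio * base / 2
  chroms <- as.character(unique(seqnames(gr)))
  chrOf <- as.character(seqnames(gr))
  rows <- lapply(chroms, function(chr) {
    r <- gr$ratio[chrOf == chr]
    r <- r[is.finite(r)]
    if (length(r) < minBins) {
      warning("chromosome ", chr, " has fewer than ", minBins,
              " usable bins: no-call", call. = FALSE)
      return(data.frame(chrom = chr, nBins = length(r),
                        ratioMedian = NA_real_, event = "no-call",
                        f = NA_real_, copyEstimate = NA_real_,
                        consistent = NA_real_, status = NA_character_))
    }
    med <- median(r)
    dev <- med - base
    f <- round(min(abs(dev), 1), 10)
    copyEst <- round(med)
    if (dev > 0 && med >= multiCut) f <- 1
    dirFrac <- if (dev == 0) 0 else mean(sign(r - base) == sign(dev))
    event <- "none"
    status <- .statusFromF(f)
    if (f >= euploidMax) {
      if (dirFrac >= consistency) {
        event <- if (dev > 0) "gain" else "loss"
      } else {
        # direction not uniform along the chromosome: leave for segmental
        event <- "none"
        status <- "euploid"
        f <- round(f, 10)
      }
    }
    data.frame(chrom = chr, nBins = length(r), ratioMedian = med,
               event = event, f = f, copyEstimate = copyEst,
               consistent = dirFrac, status = status)
  })
  cc <- do.call(rbind, rows)
  rownames(cc) <- NULL
  new("CopyNumberProfile", bins = gr, baseline = base,
      chromCalls = cc, segCalls = cn@segCalls)
}

#' Call segmental copy-number events
#'
#' Scans chromosomes without a whole-chromosome call for maximal runs of
#' consecutive bins whose (running-median smoothed) ratio deviates from
#' baseline beyond the euploid threshold in a consistent direction. Runs
#' spanning at least `minLenBp` are reported with their direction, raw-ratio
#' median and abnormal-cell fraction. Smoothing (window `smoothK` bins)
#' stops single noisy bins from fragmenting true segments at low coverage.
#'
#' @param cn a [CopyNumberProfile-class]; chromosome calls should be
#'   populated first so whole-chromosome events are not duplicated.
#' @param minLenBp minimum segment length in bp (genome coordinates).
#' @param euploidMax deviation threshold (abnormal-cell fraction scale).
#' @param smoothK running-median window (odd; shrunk on short chromosomes).
#' @return the profile with `segCalls` populated.
#' @export
callSegmentalCNVs <- function(cn, minLenBp = 10e6, euploidMax = 0.30,
                              smoothK = 15L) {
  stopifnot(is(cn, "CopyNumberProfile"))
  gr <- cn@bins
  base <- cn@baseline
  cc <- cn@chromCalls
  skip <- if (!is.null(cc)) cc$chrom[cc$event %in% c("gain", "loss")] else character(0)
  chrOf <- as.character(seqnames(gr))
  out <- list()
  for (chr in setdiff(unique(chrOf), skip)) {
    sel <- which(chrOf == chr)
    r <- gr$ratio[sel]
    ok <- is.finite(r)
    if (sum(ok) < 5L) next
    k <- min(smoothK, sum(ok))
    if (k %% 2L == 0L) k <- k - 1L
    sm <- rep(NA_real_, length(r))
    sm[ok] <- stats::runmed(r[ok], k = max(k, 1L), endrule = "median")
    state <- ifelse(!is.finite(sm), 0L,
                    ifelse(sm - base >= euploidMax, 1L,
                           ifelse(sm - base <= -euploidMax, -1L, 0L)))
    rl <- rle(state)
    endIdx <- cumsum(rl$lengths)
    startIdx <- endIdx - rl$lengths + 1L
    for (i in seq_along(rl$values)) {
      if (rl$values[i] == 0L) next
      b <- sel[startIdx[i]:endIdx[i]]
      lenBp <- max(end(gr)[b]) - (min(start(gr)[b]) - 1L)
      if (lenBp < minLenBp) next
      segMed <- median(gr$ratio[b], na.rm = TRUE)
      f <- round(min(abs(segMed - base), 1), 10)
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = min(start(gr)[b]) - 1L, end = max(end(gr)[b]),
        nBins = length(b), event = if (rl$values[i] > 0) "gain" else "loss",
        ratioMedian = segMed, f = f, status = .statusFromF(f))
    }
  }
  segs <- if (length(out)) do.call(rbind, out)
  else data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                  nBins = integer(0), event = character(0),
                  ratioMedian = numeric(0), f = numeric(0),
                  status = character(0))
  rownames(segs) <- NULL
  new("CopyNumberProfile", bins = gr, baseline = base,
      chromCalls = cc, segCalls = segs)
}

#' Classify an embryo from its copy-number calls
#'
#' Counts whole-chromosome events with aneuploid status (abnormal-cell
#' fraction above 70%): 1-2 such events give simple aneuploidy (`"SA"`),
#' three or more give complex aneuploidy (`"CA"`). Embryos whose only events
#' are whole-chromosome mosaics or segmental calls are `"other"`; embryos
#' with no events at all are euploid (`"E"`). Sex chromosomes are excluded
#' from the SA/CA count by default.
#'
#' @param cn a [CopyNumberProfile-class] with chromosome (and ideally
#'   segmental) calls populated.
#' @param excludeChroms chromosomes excluded from the whole-chromosome
#'   abnormality count.
#' @return list with `class` (`"E"`, `"SA"`, `"CA"`, `"other"`) and
#'   `wholeChromCount`.
#' @export
classifyEmbryo <- function(cn, excludeChroms = c("X", "Y")) {
  stopifnot(is(cn, "CopyNumberProfile"))
  cc <- cn@chromCalls
  if (is.null(cc)) stop("chromosome calls must be populated first")
  counted <- !(cc$chrom %in% excludeChroms)
  isEvent <- cc$event %in% c("gain", "loss")
  nAneu <- sum(counted & isEvent & cc$status %in% "aneuploid")
  nMosaic <- sum(isEvent & cc$status %in% "mosaic")
  nSeg <- if (is.null(cn@segCalls)) 0L else nrow(cn@segCalls)
  cls <- if (nAneu >= 3L) "CA"
  else if (nAneu >= 1L) "SA"
  else if (nMosaic > 0L || nSeg > 0L) "other"
  else "E"
  list(class = cls, wholeChromCount = nAneu)
}
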