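.EMBRYO_CLASSES <- c("E", "SA", "CA", "other")

.checkRecords <- function(records) {
  need <- c("couple", "embryo", "class", "wholeChromCount")
  if (!all(need %in% names(records)))
    stop("embryo records need columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(records$class), .EMBRYO_CLASSES)
  if (length(bad)) stop("unknown embryo class: ", paste(bad, collapse = ", "))
  invisible(records)
}

#' Per-class embryo proportions
#'
#' Counts and percentages (half-up, one decimal) of euploid (E), simple
#' aneuploid (SA), complex aneuploid (CA) and other (mosaic/segmental)
#' embryos.
#'
#' @param records data.frame with columns `couple, embryo, class,
#'   wholeChromCount`.
#' @return data.frame `class, count, pct` over all four classes.
#' @examples
#' rec <- data.frame(couple = 1, embryo = 1:4,
#'                   class = c("CA", "CA", "SA", "E"), wholeChromCount = c(4, 5, 1, 0))
#' categoryProportions(rec)
#' @export
categoryProportions <- function(records) {
  .checkRecords(records)
  if (!nrow(records)) stop("need at least one embryo record")
  counts <- table(factor(records$class, levels = .EMBRYO_CLASSES))
  data.frame(class = .EMBRYO_CLASSES, count = as.integer(counts),
             pct = roundHalfUp(100 * as.integer(counts) / nrow(records), 1))
}

#' Proportion of couples producing exclusively one class of embryo
#'
#' @param records embryo record table (see [categoryProportions()]).
#' @param targetClass class required for every embryo of a couple
#'   (default `"CA"`).
#' @return percentage of couples (half-up, one decimal).
#' @export
coupleExclusivity <- function(records, targetClass = "CA") {
  .checkRecords(records)
  if (!nrow(records)) stop("need at least one couple")
  allTarget <- vapply(split(records$class, records$couple),
                      function(cl) all(cl == targetClass), logical(1))
  roundHalfUp(100 * sum(allTarget) / length(allTarget), 1)
}

#' Proportion of aneuploid embryos with an abnormality count in a band
#'
#' Aneuploid means class SA or CA. The band is inclusive on both ends.
#'
#' @param records embryo record table.
#' @param lo,hi inclusive band of whole-chromosome abnormality counts.
#' @return percentage of aneuploid embryos (half-up, one decimal).
#' @export
abnormalityBand <- function(records, lo, hi) {
  .checkRecords(records)
  aneu <- records[records$class %in% c("SA", "CA"), , drop = FALSE]
  if (!nrow(aneu)) stop("no aneuploid embryos in the record set")
  inBand <- aneu$wholeChromCount >= lo & aneu$wholeChromCount <= hi
  roundHalfUp(100 * sum(inBand) / nrow(aneu), 1)
}

#' Overall aneuploidy rate (SA + CA) of a record set
#'
#' @param records embryo record table.
#' @return percentage (half-up, one decimal).
#' @export
aneuploidyRate <- function(records) {
  .checkRecords(records)
  if (!nrow(records)) stop("need at least one embryo record")
  roundHalfUp(100 * mean(records$class %in% c("SA", "CA")), 1)
}

#' Two-sample t test (classical unpaired Student form)
#'
#' Pooled-variance Student t by default (`welch = TRUE` switches to the
#' Welch form), two-tailed. If both groups have zero variance and equal
#' means the conventional `t = 0, p = 1` is returned; zero variance with
#' unequal means is an error.
#'
#' @param groupA,groupB numeric vectors, each of length at least 2.
#' @param welch use the Welch (unequal-variance) form instead of the pooled
#'   one.
#' @return list with `t`, `df`, `p`.
#' @export
twoSampleTTest <- function(groupA, groupB, welch = FALSE) {
  stopifnot(length(groupA) >= 2L, length(groupB) >= 2L)
  va <- stats::var(groupA); vb <- stats::var(groupB)
  if (va == 0 && vb == 0) {
    if (isTRUE(all.equal(mean(groupA), mean(groupB))))
      return(list(t = 0, df = length(groupA) + length(groupB) - 2L, p = 1))
    stop("zero pooled variance with unequal means: t statistic undefined")
  }
  ht <- t.test(groupA, groupB, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Reconstruct per-embryo records from aggregate cohort tallies
#'
#' Expands published-style aggregate counts (total embryos, complex and
#' simple aneuploid counts, couples, number of couples with exclusively
#' complex aneuploid embryos, number of aneuploid embryos inside an
#' abnormality-count band) into a deterministic per-embryo record table
#' whose aggregates reproduce the inputs exactly. The per-couple layout and
#' the abnormality counts of embryos outside the stated band are arbitrary
#' (any arrangement consistent with the tallies); embryos not accounted
#' for by the aneuploid classes are recorded as euploid.
#'
#' @param total total embryos.
#' @param ca complex aneuploid embryos (3 or more abnormalities each).
#' @param sa simple aneuploid embryos (1-2 abnormalities each).
#' @param couples number of couples (`NULL`: one embryo per couple).
#' @param exclusiveCA couples whose embryos are all CA.
#' @param bandCount aneuploid embryos with abnormality count inside
#'   `bandRange` (`NULL`: all CA embryos get count 4, SA count 1).
#' @param bandRange inclusive abnormality-count band.
#' @return embryo record table (see [categoryProportions()]).
#' @export
expandCohortRecords <- function(total, ca, sa, couples = NULL,
                                exclusiveCA = 0L, bandCount = NULL,
                                bandRange = c(4, 15)) {
  stopifnot(ca + sa <= total, exclusiveCA * 2 <= ca || exclusiveCA == 0)
  nE <- total - ca - sa
  inBandVal <- max(bandRange[1], 4)
  if (is.null(bandCount)) bandCount <- 0L
  stopifnot(bandCount <= ca + sa)
  # abnormality counts: `bandCount` CA embryos inside the band, the rest
  # of the CA at 3 (below a band starting at 4), SA at 1
  caCounts <- c(rep(inBandVal, min(bandCount, ca)),
                rep(3, ca - min(bandCount, ca)))
  saCounts <- rep(1, sa)
  classes <- c(rep("CA", ca), rep("SA", sa), rep("E", nE))
  counts <- c(caCounts, saCounts, rep(0, nE))
  if (is.null(couples)) {
    couple <- seq_len(total)
  } else {
    couple <- integer(total)
    caIdx <- seq_len(ca)
    saIdx <- ca + seq_len(sa)
    eIdx <- ca + sa + seq_len(nE)
    nextCouple <- 1L
    # exclusive couples: two CA embryos each (one if CA runs short)
    used <- 0L
    for (k in seq_len(exclusiveCA)) {
      take <- min(2L, ca - used - (exclusiveCA - k)) # leave >=1 CA per couple
      take <- max(take, 1L)
      couple[caIdx[used + seq_len(take)]] <- nextCouple
      used <- used + take
      nextCouple <- nextCouple + 1L
    }
    leftoverCA <- if (used < ca) caIdx[(used + 1L):ca] else integer(0)
    saLeft <- saIdx
    # mix remaining CA with one SA each so those couples are not exclusive
    for (i in leftoverCA) {
      couple[i] <- nextCouple
      if (length(saLeft)) {
        couple[saLeft[1]] <- nextCouple
        saLeft <- saLeft[-1]
      }
      nextCouple <- nextCouple + 1L
    }
    rest <- c(saLeft, eIdx)
    remaining <- couples - (nextCouple - 1L)
    if (remaining < 1L && length(rest))
      stop("cannot place remaining embryos: too few couples")
    if (length(rest))
      couple[rest] <- nextCouple - 1L +
        (seq_along(rest) - 1L) %% remaining + 1L
    usedCouples <- max(couple)
    if (usedCouples > couples) stop("couple layout exceeds couple count")
    if (usedCouples < couples) {
      # couples with no sequenced embryo cannot appear in the table; pad by
      # spreading E embryos if available, else fail loudly
      stop("tallies leave ", couples - usedCouples,
           " couples without embryos; adjust inputs")
    }
  }
  data.frame(couple = couple, embryo = sprintf("emb%04d", seq_len(total)),
             class = classes, wholeChromCount = counts)
}

#' Assemble a structured cohort report
#'
#' Aggregates the upstream outputs (embryo records, origin calls, sperm
#' ploidy calls, FISH frequencies) into one JSON-serializable report with
#' the configuration fingerprint. Stages passed as `NULL` are simply
#' omitted; stages expected by `require` but missing raise an error naming
#' the stage.
#'
#' @param embryoRecords embryo record table (required).
#' @param originCalls output of [callOrigins()] or NULL.
#' @param spermCalls list of [callPloidy()] results or NULL.
#' @param fishFreqs output of [fishFrequencies()] or NULL.
#' @param config named list fingerprinting seeds/thresholds.
#' @param require character vector of stage names that must be present.
#' @return nested list (the report).
#' @export
buildReport <- function(embryoRecords = NULL, originCalls = NULL,
                        spermCalls = NULL, fishFreqs = NULL,
                        config = list(),
                        require = "embryoRecords") {
  stages <- list(embryoRecords = embryoRecords, originCalls = originCalls,
                 spermCalls = spermCalls, fishFreqs = fishFreqs)
  for (st in require)
    if (is.null(stages[[st]]))
      stop("missing upstream stage: ", st)
  rep <- list(config = config)
  if (!is.null(embryoRecords)) {
    .checkRecords(embryoRecords)
    rep$embryos <- list(
      n = nrow(embryoRecords),
      nCouples = length(unique(embryoRecords$couple)),
      classProportions = categoryProportions(embryoRecords),
      aneuploidyRatePct = aneuploidyRate(embryoRecords),
      exclusivelyCAPct = coupleExclusivity(embryoRecords))
  }
  if (!is.null(originCalls)) {
    rep$origins <- list(calls = as.data.frame(originCalls),
                        summary = as.list(attr(originCalls, "summary")))
  }
  if (!is.null(spermCalls)) {
    cls <- vapply(spermCalls, function(x) x$class, character(1))
    rep$sperm <- list(n = length(cls),
                      classCounts = as.list(table(cls)))
  }
  if (!is.null(fishFreqs)) rep$fish <- fishFreqs
  rep
}

#' Write a report as canonical JSON
#'
#' @param report output of [buildReport()].
#' @param path output file.
#' @return `path`, invisibly. Identical reports write byte-identical files.
#' @export
writeReport <- function(report, path) {
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
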