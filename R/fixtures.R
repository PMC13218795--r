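#' Bundled reference cohort tallies
#'
#' Loads the bundled category counts for the reference cohorts: embryo
#' chromosomal classes of a recurrent blastulation-failure cohort (103
#' embryos / 50 couples) and its sporadic control (58 embryos / 30
#' couples), the exome-screen carrier tallies (109 individuals), and a
#' large PGT-tested blastocyst background cohort. Only aggregate counts are
#' stored; [expandCohortRecords()] reconstructs a per-embryo record table
#' consistent with them.
#'
#' @return data.frame with columns `cohort, item, value`.
#' @examples
#' counts <- loadCohortCounts()
#' subset(counts, cohort == "rgqbf_embryos")
#' @export
loadCohortCounts <- function() {
  path <- system.file("extdata", "cohort_counts.csv", package = "meiocnv",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Look up one tally from the cohort-counts table
#' @param counts output of [loadCohortCounts()].
#' @param cohort,item row selector.
#' @return the numeric value.
#' @export
cohortCount <- function(counts, cohort, item) {
  v <- counts$value[counts$cohort == cohort & counts$item == item]
  if (length(v) != 1L) stop("no unique tally for ", cohort, "/", item)
  v
}
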