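#' Write / read binned depth profiles as TSV
#'
#' Columns `chrom, start, end, gc, count` with 0-based half-open
#' coordinates.
#'
#' @param profile a [BinnedDepthProfile-class].
#' @param path output file.
#' @return `path` invisibly (writer); a [BinnedDepthProfile-class]
#'   (reader).
#' @export
writeBinTsv <- function(profile, path) {
  stopifnot(is(profile, "BinnedDepthProfile"))
  gr <- profile@bins
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   gc = gr$gc, count = gr$count)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBinTsv
#' @param baseline `"diploid"` or `"haploid"`.
#' @param normalized whether counts in the file are already GC-normalized.
#' @export
readBinTsv <- function(path, baseline = c("diploid", "haploid"),
                       normalized = FALSE) {
  baseline <- match.arg(baseline)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gc", "count")
  if (!all(need %in% names(df)))
    stop("bin TSV needs columns: ", paste(need, collapse = ", "))
  gr <- GRanges(as.character(df$chrom),
                IRanges(start = df$start + 1L, end = df$end))
  gr$gc <- df$gc
  gr$count <- df$count
  new("BinnedDepthProfile", bins = gr, baseline = baseline,
      normalized = normalized)
}

#' Write / read SNP allele-count tables as TSV
#'
#' Columns `chrom, pos, ref_count, alt_count, father_gt, mother_gt` with
#' 1-based positions.
#'
#' @param alleleCounts an [AlleleCountTable-class].
#' @param path output file.
#' @return `path` invisibly (writer); an [AlleleCountTable-class] (reader).
#' @export
writeAlleleTsv <- function(alleleCounts, path) {
  stopifnot(is(alleleCounts, "AlleleCountTable"))
  gr <- alleleCounts@loci
  df <- data.frame(chrom = as.character(seqnames(gr)), pos = start(gr),
                   ref_count = gr$refCount, alt_count = gr$altCount,
                   father_gt = gr$fatherGT, mother_gt = gr$motherGT)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAlleleTsv
#' @export
readAlleleTsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref_count", "alt_count", "father_gt",
            "mother_gt")
  if (!all(need %in% names(df)))
    stop("allele TSV needs columns: ", paste(need, collapse = ", "))
  gr <- GRanges(as.character(df$chrom), IRanges(start = df$pos, width = 1L))
  gr$refCount <- as.integer(df$ref_count)
  gr$altCount <- as.integer(df$alt_count)
  gr$fatherGT <- df$father_gt
  gr$motherGT <- df$mother_gt
  new("AlleleCountTable", loci = gr)
}

#' Write a ground-truth karyotype as TSV
#'
#' One row per chromosome (`chrom, maternal_copies, paternal_copies,
#' events`), with segmental/mosaic events encoded as
#' `start-end:delta:parent:f` separated by `;`.
#'
#' @param truth an [EmbryoTruth-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTruthTsv <- function(truth, path) {
  stopifnot(is(truth, "EmbryoTruth"))
  chroms <- names(truth@maternalCopies)
  ev <- truth@events
  evStr <- vapply(chroms, function(chr) {
    e <- ev[ev$chrom == chr, , drop = FALSE]
    if (!nrow(e)) return("")
    paste(sprintf("%d-%d:%+d:%s:%g", as.integer(e$start), as.integer(e$end),
                  as.integer(e$delta), e$parent, e$f), collapse = ";")
  }, character(1))
  df <- data.frame(chrom = chroms,
                   maternal_copies = as.integer(truth@maternalCopies),
                   paternal_copies = as.integer(truth@paternalCopies),
                   events = evStr)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write CNV calls (chromosome-level and segmental) as TSV
#'
#' Columns `chrom, start, end, type, scope, ratio, f, status`; whole
#' chromosomes span their full length.
#'
#' @param cn a [CopyNumberProfile-class] with calls populated.
#' @param path output file.
#' @param genome optional [GenomeModel-class] for chromosome ends (else
#'   inferred from the bins).
#' @return `path`, invisibly.
#' @export
writeCnvCallsTsv <- function(cn, path, genome = NULL) {
  stopifnot(is(cn, "CopyNumberProfile"))
  cc <- cn@chromCalls
  if (is.null(cc)) stop("chromosome calls must be populated first")
  gr <- cn@bins
  chrEnd <- vapply(split(end(gr), as.character(seqnames(gr))), max,
                   numeric(1))
  if (!is.null(genome)) chrEnd <- genome@seqlens[names(chrEnd)]
  rows <- data.frame(chrom = cc$chrom, start = 0,
                     end = as.numeric(chrEnd[cc$chrom]),
                     type = cc$event, scope = "chromosome",
                     ratio = cc$ratioMedian, f = cc$f, status = cc$status)
  sc <- cn@segCalls
  if (!is.null(sc) && nrow(sc))
    rows <- rbind(rows, data.frame(chrom = sc$chrom, start = sc$start,
                                   end = sc$end, type = sc$event,
                                   scope = "segment", ratio = sc$ratioMedian,
                                   f = sc$f, status = sc$status))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write parental genotypes as a minimal GT-only VCF
#'
#' Emits a VCFv4.2 file with abstract `A`/`B` alleles (REF/ALT), phased GT
#' fields for FATHER and MOTHER, the population B-allele frequency as
#' `AF`, and contig headers from the genome model. [readParentalVcf()]
#' round-trips it via the `vcfR` package.
#'
#' @param parents a [ParentalGenotypes-class].
#' @param path output file (plain text, uncompressed).
#' @return `path`, invisibly.
#' @export
writeParentalVcf <- function(parents, path) {
  stopifnot(is(parents, "ParentalGenotypes"))
  panel <- parents@panel
  gr <- panel@loci
  sl <- panel@genome@seqlens
  hdr <- c("##fileformat=VCFv4.2",
           "##source=meiocnv",
           sprintf("##contig=<ID=%s,length=%d>", names(sl), as.integer(sl)),
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Population B-allele frequency\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "FATHER", "MOTHER", sep = "\t"))
  gt <- function(h) paste0(h[, 1], "|", h[, 2])
  body <- paste(as.character(seqnames(gr)), start(gr), ".", "A", "B", ".",
                "PASS", sprintf("AF=%.6f", gr$popBaf), "GT",
                gt(parents@father), gt(parents@mother), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read parental genotypes from a GT-only VCF
#'
#' Uses `vcfR` to parse the file written by [writeParentalVcf()] (or any
#' biallelic VCF with phased/unphased GT for two samples named FATHER and
#' MOTHER and an AF INFO field). Unphased heterozygotes are assigned a
#' deterministic phase (REF first).
#'
#' @param path VCF file.
#' @param genome a [GenomeModel-class] covering the file's chromosomes.
#' @return a [ParentalGenotypes-class].
#' @export
readParentalVcf <- function(path, genome) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (!all(c("FATHER", "MOTHER") %in% colnames(gt)))
    stop("VCF must contain FATHER and MOTHER samples")
  af <- as.numeric(sub(".*AF=([0-9.eE+-]+).*", "\\1",
                       vcfR::getINFO(v)))
  gr <- GRanges(fix[, "CHROM"],
                IRanges(start = as.integer(fix[, "POS"]), width = 1L))
  gr$popBaf <- af
  panel <- new("SnpPanel", loci = gr, genome = genome)
  parseGT <- function(x) {
    parts <- strsplit(unname(x), "[|/]")
    unname(t(vapply(parts, function(p) as.integer(p[1:2]), integer(2))))
  }
  new("ParentalGenotypes", panel = panel,
      father = parseGT(gt[, "FATHER"]), mother = parseGT(gt[, "MOTHER"]))
}
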