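#' Functional classes retained by the variant filter
#' @keywords internal
.KEEP_CLASSES <- c("frameshift-indel", "inframe-indel", "nonsynonymous-SNV",
                   "stopgain", "splice-site")

#' Filter annotated variants by frequency, impact, and gene panel
#'
#' Three gates, all required: (i) population frequency below `mafCut` in the
#' reference databases (gnomAD and ExAC columns; missing frequencies are
#' treated as 0, i.e. rare -- a documented risk); (ii) functional impact in
#' coding indels, nonsynonymous SNVs, stopgains, or splice-site changes
#' (synonymous and other classes are removed); (iii) gene on the supplied
#' panel. By default a variant must be rare in every database
#' (`combine = "max"`); `combine = "min"` requires rarity in at least one.
#'
#' @param variants data.frame with one row per variant per sample; columns
#'   `sample, gene, chrom, pos, ref, alt, class, zygosity, gnomad, exac`.
#' @param panel character vector of panel gene symbols (upper-cased).
#' @param mafCut minor-allele-frequency cutoff (default 0.01).
#' @param combine how the databases are combined before the cutoff.
#' @return the surviving subset of `variants` (same columns).
#' @export
filterVariants <- function(variants, panel, mafCut = 0.01,
                           combine = c("max", "min")) {
  combine <- match.arg(combine)
  need <- c("sample", "gene", "class", "zygosity", "gnomad", "exac")
  if (!all(need %in% names(variants)))
    stop("variants need columns: ", paste(need, collapse = ", "))
  if (!length(panel)) stop("empty gene panel")
  g <- ifelse(is.na(variants$gnomad), 0, variants$gnomad)
  e <- ifelse(is.na(variants$exac), 0, variants$exac)
  freq <- if (combine == "max") pmax(g, e) else pmin(g, e)
  keep <- freq < mafCut &
    variants$class %in% .KEEP_CLASSES &
    toupper(variants$gene) %in% toupper(panel)
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect carrier genotypes compatible with recessive inheritance
#'
#' Per sample and gene: `"homozygous"` if any surviving variant is
#' homozygous; `"potential-compound-het"` if the sample carries two or more
#' distinct heterozygous variants in the gene (duplicate records of the same
#' variant are collapsed by locus and alleles first, so they can never fake
#' a compound het); `"none"` otherwise.
#'
#' @param variants a filtered variant table (see [filterVariants()]) with
#'   `chrom, pos, ref, alt` available for deduplication.
#' @return data.frame `sample, gene, model` with one row per sample-gene
#'   pair that has at least one variant.
#' @export
detectCarriers <- function(variants) {
  if (!nrow(variants))
    return(data.frame(sample = character(0), gene = character(0),
                      model = character(0)))
  key <- paste(variants$sample, variants$gene, variants$chrom, variants$pos,
               variants$ref, variants$alt, sep = "\r")
  v <- variants[!duplicated(key), , drop = FALSE]
  sg <- paste(v$sample, v$gene, sep = "\r")
  rows <- lapply(split(seq_len(nrow(v)), sg), function(ii) {
    vv <- v[ii, , drop = FALSE]
    model <- if (any(vv$zygosity == "hom")) "homozygous"
    else if (sum(vv$zygosity == "het") >= 2L) "potential-compound-het"
    else "none"
    data.frame(sample = vv$sample[1], gene = vv$gene[1], model = model)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sample, out$gene), , drop = FALSE]
}

#' Cohort carrier rate
#'
#' Distinct samples carrying a recessive-compatible genotype (homozygous or
#' potential compound het) divided by the cohort size, as a percentage
#' rounded half-up to one decimal.
#'
#' @param carriers output of [detectCarriers()].
#' @param nSamples cohort size.
#' @return percentage (one decimal).
#' @examples
#' carrierRate(data.frame(sample = paste0("S", 1:20), gene = "MEI1",
#'                        model = "homozygous"), 109) # 18.3
#' @export
carrierRate <- function(carriers, nSamples) {
  stopifnot(nSamples > 0)
  n <- length(unique(carriers$sample[carriers$model != "none"]))
  roundHalfUp(100 * n / nSamples, 1)
}

#' Read a gene panel from a newline-delimited text file
#'
#' @param path file with one gene symbol per line (blank lines and `#`
#'   comments ignored).
#' @return upper-cased character vector of symbols.
#' @export
readGenePanel <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (!length(x)) stop("empty gene panel file")
  toupper(unique(x))
}

#' Simulate an annotated WES variant cohort with known carriers
#'
#' Builds a per-sample annotated variant table in which a chosen number of
#' samples carry a homozygous rare functional panel variant, a further group
#' carries two distinct heterozygous panel variants in one gene, and every
#' sample additionally carries decoy variants that the filter chain must
#' remove (common variants, synonymous rare variants, rare functional
#' variants off the panel) plus occasional single rare heterozygous panel
#' variants that do not make a carrier genotype.
#'
#' @param nSamples cohort size.
#' @param nHom number of homozygous carriers.
#' @param nCompHet number of potential compound-het carriers.
#' @param panel gene panel (symbols) to place carrier variants in.
#' @param seed RNG seed.
#' @return data.frame in the [filterVariants()] input layout.
#' @export
simulateVariantCohort <- function(nSamples = 109, nHom = 13, nCompHet = 7,
                                  panel, seed = NULL) {
  stopifnot(nHom + nCompHet <= nSamples, length(panel) >= 1)
  panel <- toupper(panel)
  withSeed(seed, {
    samples <- sprintf("S%03d", seq_len(nSamples))
    carrierIds <- sample(samples, nHom + nCompHet)
    homIds <- carrierIds[seq_len(nHom)]
    chetIds <- setdiff(carrierIds, homIds)
    mkRow <- function(sample, gene, pos, cls, zyg, gnomad = NA, exac = NA)
      data.frame(sample = sample, gene = gene, chrom = "22", pos = pos,
                 ref = "A", alt = "G", class = cls, zygosity = zyg,
                 gnomad = gnomad, exac = exac)
    rows <- list()
    for (s in homIds)
      rows[[length(rows) + 1L]] <- mkRow(
        s, sample(panel, 1), sample.int(5e7, 1),
        sample(.KEEP_CLASSES, 1), "hom", gnomad = 0.0002)
    for (s in chetIds) {
      g <- sample(panel, 1)
      ps <- sample.int(5e7, 2)
      rows[[length(rows) + 1L]] <- mkRow(s, g, ps[1],
                                         sample(.KEEP_CLASSES, 1), "het")
      rows[[length(rows) + 1L]] <- mkRow(s, g, ps[2],
                                         sample(.KEEP_CLASSES, 1), "het",
                                         exac = 0.0001)
    }
    for (s in samples) {
      # decoys removed by each gate, plus a lone het that is not a carrier
      rows[[length(rows) + 1L]] <- mkRow(s, sample(panel, 1),
                                         sample.int(5e7, 1),
                                         "nonsynonymous-SNV", "het",
                                         gnomad = 0.05)
      rows[[length(rows) + 1L]] <- mkRow(s, sample(panel, 1),
                                         sample.int(5e7, 1),
                                         "synonymous", "hom")
      rows[[length(rows) + 1L]] <- mkRow(s, "OFFPANELGENE",
                                         sample.int(5e7, 1), "stopgain",
                                         "hom")
      if (runif(1) < 0.3 && !(s %in% carrierIds))
        rows[[length(rows) + 1L]] <- mkRow(s, sample(panel, 1),
                                           sample.int(5e7, 1),
                                           "nonsynonymous-SNV", "het")
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
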