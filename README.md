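# meiocnv

Simulation and inference of meiotic aneuploidy from low-coverage
single-cell sequencing.

## What this is for

Recurrent blastulation failure — morphologically good Day-3 embryos that
repeatedly fail to form blastocysts — is often driven by gamete-derived
complex aneuploidy: meiotic gene variants disturb chromosome segregation in
oogenesis or spermatogenesis, and the resulting embryos carry many
whole-chromosome abnormalities. `meiocnv` implements the computational
pipeline such a study needs, plus a synthetic-data generator with known
ground truth to validate every step:

* **simkit** — parents under Hardy–Weinberg, full meiotic tetrads with
  MI/MII nondisjunction and whole-genome (unreduced-gamete) diploidy,
  embryos with whole-chromosome / segmental / mosaic events, and their
  observables: negative-binomial binned read depth with GC bias, and
  SNP allele counts with MDA-style allele dropout.
* **depthcnv** — LOWESS GC normalization, copy ratios on a diploid
  (embryo) or haploid (sperm) baseline, whole-chromosome and segmental CNV
  calls with abnormal-cell-fraction estimates
  (euploid < 30% ≤ mosaic ≤ 70% < aneuploid), and embryo classification:
  E (euploid), SA (1–2 whole-chromosome abnormalities), CA (≥ 3), other
  (mosaic/segmental only).
* **spermploidy** — the heterozygosity index
  `HI = log2(R_sample / R_diploid)` (haploid ≈ −1 or below, diploid ≈ 0),
  integrated with the CNV profile into a per-cell ploidy call; FISH count
  frequencies.
* **origin** — parental origin of embryonic gains and losses from
  informative SNP patterns (father AA / mother BB and the reciprocal): a
  B-allele-frequency Z test per pattern (maternal duplication:
  `Z_AABB > +3` with `Z_BBAA < −3`; paternal: reversed) and genotype-ratio
  rules for losses (AABB-BB ratio > 0.8 → paternal loss; AABB-AA
  ratio > 0.8 → maternal loss).
* **variantscreen** — the rare-variant filter chain (MAF < 1%, functional
  impact, gene panel) and recessive-carrier detection (homozygous or ≥ 2
  distinct heterozygous variants per gene).
* **cohort** — class proportions, couple-level exclusivity,
  abnormality-count bands, Student t comparisons, and a JSON report.

Data containers are Bioconductor-style S4 classes built on `GenomicRanges`
(`SnpPanel`, `BinnedDepthProfile`, `CopyNumberProfile`,
`AlleleCountTable`, …), with TSV and GT-only VCF readers/writers for real
data.

## Worked example

Simulate a couple, an embryo with two maternal trisomies and one paternal
monosomy, and run depth-based calling plus origin assignment:

```r
library(meiocnv)

gm <- genomeModel(as.character(c(1, 2, 14, 15, 16, 21)))
panel <- snpPanel(gm, nPerChrom = 900, seed = 1)
parents <- simulateParents(panel, seed = 2)

# diploid control embryo used as the depth reference
control <- formEmbryo(simulateGamete(parents, "father", seed = 10),
                      simulateGamete(parents, "mother", seed = 11))
bins <- binGenome(gm, 1e4, seed = 4)
ref <- gcNormalize(simulateBinDepth(control, bins, noiseModel(), seed = 12))

events <- data.frame(chrom = c("2", "16", "21"),
                     parent = c("maternal", "maternal", "paternal"),
                     type = c("gain", "gain", "loss"))
truth <- simulateAneuploidEmbryo(parents, events, seed = 3)
depth <- simulateBinDepth(truth, bins, noiseModel(), seed = 5)
cn <- callChromosomeCNVs(copyRatioProfile(gcNormalize(depth), ref))
subset(chromCalls(cn), select = -consistent)
#>   chrom nBins ratioMedian event      f copyEstimate    status
#> 1     1  2493        1.95  none 0.0470            2   euploid
#> 2     2  2432        2.95  gain 0.9535            3 aneuploid
#> 3    14  1074        1.95  none 0.0467            2   euploid
#> 4    15  1026        1.96  none 0.0410            2   euploid
#> 5    16   904        3.04  gain 1.0000            3 aneuploid
#> 6    21   482        1.02  loss 0.9767            1 aneuploid

classifyEmbryo(cn)
#> $class
#> [1] "CA"
#> $wholeChromCount
#> [1] 3

alleles <- simulateAlleleCounts(truth, parents, noiseModel(), seed = 6)
callOrigins(cn, alleles)
#>   region       event   origin zAABB zBBAA aaRatio bbRatio nLoci
#> 1      2 duplication maternal  7.74 -6.98      NA      NA    61
#> 2     16 duplication maternal  9.52 -8.53      NA      NA    87
#> 3     21        loss paternal    NA    NA       0       1    33
```

Reading the output: both trisomies sit at copy ratio ≈ 3 with estimated
abnormal-cell fraction ≈ 1 (constitutive), the monosomy at ratio ≈ 1, so
the embryo is complex aneuploid (3 whole-chromosome events). The positive
`Z_AABB` with concurrent negative `Z_BBAA` identifies the extra copies as
maternal; at informative loci on the lost chromosome every read carries the
maternal B allele (`bbRatio = 1`), identifying the loss as paternal.
Ploidy calling for single sperm works the same way on a haploid baseline —
see `analyzeSperm()`, `heterozygosityIndex()` and the vignette
(`vignettes/meiocnv-methods.Rmd`).

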