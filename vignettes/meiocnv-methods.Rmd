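---
title: "Models and methods behind meiocnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meiocnv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiocnv)
```

## The scientific problem

Some couples repeatedly produce morphologically good cleavage-stage embryos
that never form blastocysts. A leading explanation is gamete-derived complex
aneuploidy: variants in meiotic genes disturb chromosome segregation during
oogenesis or spermatogenesis, so morphologically normal embryos carry many
whole-chromosome abnormalities and arrest around the morula stage. Testing
that hypothesis requires several bespoke computations on low-coverage
single-cell sequencing data:

* copy-number and ploidy inference for single sperm and whole arrested
  embryos from binned read depth;
* a heterozygosity index separating haploid from diploid sperm where read
  depth alone cannot;
* parental-origin assignment of embryonic gains and losses from informative
  SNP patterns;
* a rare-variant filter chain with recessive-carrier detection; and
* cohort-level classification statistics.

`meiocnv` implements this pipeline end to end and pairs it with a
synthetic-data generator whose ground truth is known, so every inference
step can be validated quantitatively.

## The meiosis model

Parents are simulated as two haplotypes per locus under Hardy–Weinberg
equilibrium at each SNP's population B-allele frequency. One meiosis
produces the full tetrad:

* each chromosome is replicated into four chromatids (two sisters per
  homolog);
* crossovers (default one per chromosome, position uniform) exchange the
  segment distal to the exchange point between one chromatid of each
  homolog, on the arm where the crossover falls — so the
  centromere-proximal genotype always tracks the centromere;
* meiosis I separates homologs, meiosis II separates sisters.

Nondisjunction is modelled per chromosome: an MI error sends both homologs
to one pole (two products receive one chromatid of *each* homolog — disomic
and heterozygous near the centromere — and two receive none), an MII error
keeps two sisters together (one disomic homozygous product, one nullisomic,
two normal). Error specifications accept an orientation suffix
(`"MI+"`/`"MI-"`) so scenario code can choose whether the transmitted
product is the disomic or the nullisomic one; the bare form randomizes the
pole, as in the unordered biology. Summing copies over the four products
always gives exactly four of every chromosome, which the test suite checks
over ten thousand random meioses.

Whole-genome diploidy is modelled as an *unreduced* gamete: two products
carry one chromatid of each homolog for every chromosome. This choice (over
duplicating a single chromatid set) is deliberate: observed diploid sperm
show balanced heterozygosity (HI near 0), which only a gamete retaining both
homologs can produce. Such gametes still show regional loss of
heterozygosity distal to crossovers — the same regional
hetero-/homozygosity patterns used to flag potential diploidy in real data.

Sex chromosomes are carried through the machinery as autosome-like
placeholders (every simulated parent is disomic for X and Y, every gamete
transmits one of each). Karyotype realism for X/Y is not attempted; they
are excluded from aneuploidy counting by default.

## Sequencing observables

**Binned depth.** Counts per bin are negative-binomial with mean
proportional to the local copy number times a monotone GC efficiency
(`exp(slope * (gc - 0.45))`, normalized to mean 1). Mosaic events add
`f × delta` to the local copy number, so a 50% mosaic single-copy gain
raises the expected depth ratio to 1.25. The mean is absolute — reads
scale with DNA content — so an unreduced diploid sperm yields about twice
the reads of a haploid one.

**Allele counts.** Reads at each SNP are drawn from the cell's weighted
allele pool. Each copy drops out independently with the MDA-style dropout
probability (default 0.10 per haplotype for single cells, 0 for bulk
parental DNA), and each read reports the opposite allele with the
sequencing-error probability (default 0.01). Loci whose whole pool drops
out return zero depth.

**Default noise scales.** The defaults mirror the study design being
emulated: roughly 10 M single-end reads per embryo in 10-kb bins and 5 M
reads per sperm in 20-kb bins, i.e. ~32 reads per bin at the baseline copy
number in both assays. The abstract genome uses hg19-like chromosome
lengths scaled by 0.1 (a ~310 Mb genome), keeping the per-bin and per-locus
statistics of the real assays while making simulations fast; the read
budget scales with the genome. The negative-binomial size is 40, giving a
per-bin coefficient of variation of about 0.24 at the diploid baseline —
at 32 reads per bin the Poisson floor alone is 0.18, so a substantially
smaller CV is not attainable at this depth, and all chromosome-scale
statistics are medians over hundreds of bins where this noise is
negligible.

## Copy-number calling

GC bias is removed by a robust locally weighted regression of count on GC
(span 0.3), fitted on bins with GC in [0.3, 0.6] and non-zero counts, and
rescaled to preserve the genome-wide median. Copy ratios are
`baseline × normalized count / reference level` with baseline 2 for embryos
and 1 for sperm. The reference is either the profile's own median (which
hides uniform ploidy shifts — the reason sperm ploidy also integrates the
heterozygosity index) or a bin-matched control profile. For sperm, the
shipped reference averages several simulated haploid control cells:
dividing by a single noisy cell would roughly double the per-bin ratio
noise.

Per chromosome, the abnormal-cell fraction is estimated as
`f = |median ratio − baseline|` under a single-copy-delta assumption,
clipped to [0, 1]; multi-copy gains (ratio ≥ 3.5 on the diploid scale)
report an integer copy estimate with `f = 1`. Status follows the
cell-fraction rule: euploid below 30%, mosaic from 30% to 70% inclusive,
aneuploid above 70%. `f` is rounded to 10 decimals before comparison so
that profiles constructed exactly at a boundary classify exactly
(`2.30 − 2` in floating point is slightly below 0.30). A whole-chromosome
call also requires at least 80% of the chromosome's bins to deviate in the
call direction; otherwise the candidate is delegated to segmental calling.
Chromosomes with fewer than 10 bins are no-calls with a warning.

Segmental events are maximal runs of consecutive bins beyond the euploid
threshold in a consistent direction, at least 10 Mb long (genome
coordinates; scenario code passes scaled values). Runs are detected on a
15-bin running median — at ~32 reads per bin, single-bin votes would
fragment every true segment — while the reported `f` comes from the raw
ratios. Chromosomes that already carry a whole-chromosome call are skipped,
so events are never reported twice.

Embryos classify from the call set alone: 1–2 whole-chromosome aneuploid
events are simple aneuploidy (SA), three or more are complex (CA); embryos
whose only events are whole-chromosome mosaics or segmental calls are
"other"; event-free embryos are euploid (E). Whether segmental-only embryos
should instead count as euploid is ambiguous in the source material; we
follow the figure-legend reading ("other: mosaic or segmental
abnormalities").

## Sperm ploidy

The heterozygosity index is `HI = log2(R_sample / R_diploid)` over the same
loci, with the heterozygous-call rate defined as the fraction of loci at
depth ≥ 10 whose B-allele read fraction lies in [0.2, 0.8]. An error-free
haploid has a sample rate of exactly zero, so rates below `1e-4` are
clamped and flagged; the clamped HI (≈ −11 against a rate of 0.3) still
falls on the haploid side of the decision threshold. Why real haploid cells
sit near −1 rather than at an arbitrarily negative value is not documented
for the emulated assay — residual amplification-error heterozygous calls
are a plausible cause — so the thresholds are configuration
(`ploidyThresholds()`), defaulting to "haploid at HI ≤ −0.7, diploid within
±0.3".

The diploid reference rate is computed from a somatic diploid cell of the
same donor pushed through the same amplification noise, so dropout-driven
heterozygosity loss cancels in the ratio. Simulated diploid (unreduced)
sperm sit slightly below 0 (crossover-driven regional homozygosity removes
~10–15% of heterozygous loci), comfortably inside the ±0.3 band.

The integrated call gives CNV evidence precedence: a flat haploid-baseline
profile with haploid HI is haploid; a uniformly doubled profile (possible
only against an external haploid reference) with in-band HI is diploid, and
a doubled profile whose smoothed bins support the doubling at ≥ 80% is
called diploid even when HI drifts out of band; otherwise the
whole-chromosome event count assigns simple (1–2) or complex (≥ 3)
aneuploidy. Irreconcilable evidence returns "ambiguous" with both evidence
lines.

FISH tabulations are handled as plain count arithmetic: disomy, nullisomy
(per chromosome) and diploidy (per probe set) as percentages of the probe
set's analyzable nuclei.

## Parental origin of embryonic aneuploidies

Informative loci are those with the parents homozygous for opposite
alleles: AABB (father AA, mother BB) or BBAA. Embryo genotypes are called
from the B-allele fraction (AA < 0.1, AB in [0.2, 0.8], BB > 0.9, depth
≥ 10; these thresholds are configuration — the decision rules are defined
in genotype space, the caller itself is ours).

For a gain, the mean BAF of AB-called informative loci in the region is
compared with AB loci from event-free chromosomes:
`Z = (mean_region − mean_background) / (sd_background / sqrt(n_region))`,
separately per pattern. A maternal extra copy pushes AABB loci toward 2/3
and BBAA loci toward 1/3, so maternal duplication requires `Z_AABB > +3`
**and** `Z_BBAA < −3` (the conservative reading of "concurrent"), paternal
duplication the reverse; anything else is undetermined. For `k` extra
copies the expected BAF generalizes to `(1+k)/(2+k)` and is reported, not
thresholded. The region must contain at least 20 informative loci; the Z
itself requires at least 10 AB loci per pattern (with fewer the statistic
is returned as NA and the call is undetermined — at 10 loci the trisomy
effect is still ~6 standard errors, so this floor costs no power).

For a loss, genotype ratios among AABB loci decide: losing the paternal
copy leaves only maternal B (BB fraction > 0.8 → paternal loss), losing the
maternal copy leaves only paternal A (AA fraction > 0.8 → maternal loss).
The reciprocal BBAA loci are evaluated symmetrically as an advisory,
non-blocking consistency check, since the stated rule is defined on AABB
loci.

Swapping the parental labels maps every AABB locus to a BBAA locus while
leaving each BAF unchanged, so the Z pair swaps exactly and every
maternal/paternal call flips — a property the suite asserts on 50 random
scenarios. Whether the underlying Z-test was one- or two-sample, and
whether it pooled chromosomes, is not documented; the implemented form
(empirical background mean and SD per pattern) is the stated configuration.

## Variant screening

Three gates, all required: population frequency below 1% (missing
frequencies count as rare — the emulated annotation tables show "–" for
most candidate variants; this is a documented risk), functional class in
{coding indel, nonsynonymous SNV, stopgain, splice site}, and gene on the
panel (the package ships a small fixture panel of meiosis and infertility
genes; the real screen used a 4087-gene list not reproduced here). Whether
the 1% cutoff applies per database or to their maximum is unstated; the
default takes the maximum (stricter), with a switch. Carriers are samples
with a homozygous surviving variant or two-plus distinct heterozygous
variants in one gene, after deduplication by locus and alleles; segregation
and pathogenicity classifications are treated as pass-through annotation,
not computed.

## Cohort statistics

Percentages are rounded half-up to one decimal, matching the tabulated
presentation style. The group comparison is the classical pooled-variance
two-tailed t test (`stats::t.test(var.equal = TRUE)` under the module
surface), with a Welch switch; both-groups-constant-and-equal returns the
`t = 0, p = 1` convention. `expandCohortRecords()` reconstructs a
per-embryo record table from aggregate tallies (the only form in which the
reference cohorts are available); the per-couple layout beyond the stated
exclusivity counts, and the abnormality counts outside the stated band, are
deterministic but arbitrary, so only the tallied fractions are meaningful.

## What the simulations do and do not show

The generator reproduces the statistical structure the inference relies on:
copy-proportional overdispersed bin counts with a smooth GC bias, MDA-like
per-haplotype dropout, read-level allele sampling, and meiotically coherent
karyotypes. It does not attempt read-level simulation, alignment artifacts,
amplification waviness beyond the GC curve, position-dependent dropout, or
contamination. Passing tests therefore demonstrate that the inference
rules are correct and well calibrated for data matching these assumptions,
not that the pipeline is robust to every artifact of real amplified
single-cell libraries.

Problem sizes used by the test suite and acceptance script (chosen to keep
a full run in a couple of minutes on one core): a six-chromosome ~84 Mb
genome slice with 900 SNPs per chromosome for embryo/origin simulations,
200 origin replicates at default noise, 100 sperm cells per class for the
haploid/diploid accuracy check, and 10,000 meioses for tetrad
conservation. Classification accuracy depends on per-bin depth and
informative-locus counts, both of which match the full-scale defaults, not
on total genome size.

## Reproducing the cohort numbers

`scripts/acceptance.R` (repository root) rebuilds the bundled cohort
tallies into record tables, runs the cohort operations and the variant
filter chain, evaluates the heterozygosity index at its analytic anchor,
and writes one JSON object with the resulting values. See the README for
the command line.
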