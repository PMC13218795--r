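Package: meiocnv
Title: Simulation and Inference of Meiotic Aneuploidy from Low-Coverage
    Single-Cell Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying gamete-derived chromosomal abnormalities in
    preimplantation embryos. Provides a synthetic-data generator for parental
    SNP genotypes, gametes with meiosis I / meiosis II nondisjunction and
    whole-genome diploidy, and embryos with whole-chromosome, segmental and
    mosaic abnormalities together with their sequencing observables (binned
    read depth with GC bias, SNP allele counts with allele dropout); GC
    normalization and copy-number calling on diploid (embryo) or haploid
    (sperm) baselines with euploid/mosaic/aneuploid cell-fraction thresholds;
    single-sperm ploidy calling that integrates copy-number profiles with the
    heterozygosity index; parental-origin assignment of embryonic gains and
    losses from informative SNP patterns (B-allele-frequency Z-tests and
    genotype-ratio rules); a rare-variant filter chain with carrier detection;
    and cohort-level classification statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
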