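Package: loh6p
Title: Case-Control Association and Allelic-Imbalance Micro-Deletion Screening on Chromosome 6p
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A case-control analysis pipeline for tag-SNP panels on chromosome
    6p: marker quality control (call rate, minor allele frequency, exact
    Hardy-Weinberg test), single-SNP allelic and genotypic association with
    odds ratios and max-T permutation correction, EM haplotype-frequency
    estimation with pairwise linkage disequilibrium and confidence-interval
    haplotype blocks, a homozygosity-ratio (T/N) statistic that calls frequent
    loss-of-heterozygosity loci and adjacency-based micro-deletion regions,
    runs-of-homozygosity screening, and 2^-ddCt qPCR follow-up with paired
    tests.  Includes a synthetic-data generator emulating the study design
    (360 cases / 360 controls, 233 tag SNPs over 6-30 Mb) so every stage is
    testable without individual-level cohort genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
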