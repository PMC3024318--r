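#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# The cohort genotypes behind the published 6p analysis were never deposited,
# so every downstream stage runs on synthetic data built to the same design:
# 360 cases / 360 controls, 233 tag SNPs over 6.1-30.0 Mb, plus dedicated
# panels carrying a known risk haplotype, a 4-SNP hemizygous micro-deletion
# and autozygous tracts, and an 11-pair tumor/normal Ct table.

suppressPackageStartupMessages(library(loh6p))

out <- "results/sim"
manifest <- write_fixture_suite(out, seed = 1)
message("wrote ", length(manifest$files), " files to ", out)
message("per-fixture seeds: ",
        paste(names(manifest$seeds), unlist(manifest$seeds),
              sep = "=", collapse = ", "))
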