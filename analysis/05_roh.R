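#!/usr/bin/env Rscript
# Stage 5: runs-of-homozygosity screen.
#
# The null study-design panel (~103 kb marker spacing) should be ROH-free:
# its spacing cannot satisfy the 100-SNP / 1,000-kb segment criteria without
# a biologically implausible tract.  The dense 10-kb panel carries five
# implanted 2-Mb autozygous tracts that must all be found.

suppressPackageStartupMessages(library(loh6p))
dir.create("results/roh", recursive = TRUE, showWarnings = FALSE)

nul <- read_ped_map("results/sim/null.ped", "results/sim/null.map")
rn <- roh_summary(nul$panel, nul$phen)
message("null cohort: ", nrow(rn$segments), " ROH segment(s) in ",
        nrow(rn$per_sample), " samples")

d <- read_ped_map("results/sim/roh.ped", "results/sim/roh.map")
rd <- roh_summary(d$panel, d$phen)
write_tsv(rd$segments, "results/roh/segments.tsv")
write_tsv(rd$per_sample, "results/roh/per_sample.tsv")
message("dense cohort: ", nrow(rd$segments), " segment(s) across ",
        sum(rd$per_sample$n_segments > 0), " sample(s); mean length ",
        sprintf("%.0f kb", mean(rd$segments$length_kb)))
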