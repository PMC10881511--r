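#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates the default synthetic cohort: a wild panel, a bottlenecked selfing
# crop, de-domesticated / introgressed / F1 weed strains, one divergent
# outgroup, and two localized sweeps (one per weed strain), writing the VCF,
# population map and truth files that the later stages consume.

library(feralscan)

out <- "results/cohort"
cfg <- scenario_config(seed = 17)
co <- emit_cohort(cfg, out)

cat("cohort:", length(co$popmap$sample), "samples,",
    n_sites(co$gm), "SNPs over",
    paste(names(cfg$contig_lengths), collapse = " + "), "\n")
cat("groups:", paste(sort(unique(co$popmap$group)), collapse = ", "), "\n")
cat("truth: ", nrow(co$truth$tracts), "ancestry tracts,",
    nrow(co$truth$sweeps), "sweep intervals\n")
cat("files under", out, "\n")
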