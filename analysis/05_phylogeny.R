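#!/usr/bin/env Rscript
# Stage 5 — neighbor-joining phylogeny of the cohort.
#
# Builds the NJ tree on homozygous complete-data SNPs with JC-corrected
# distances, bootstraps it, roots it on the outgroup, and reports where the
# weed strains attach. Genome-wide heterozygotes (F1 hybrids) are excluded:
# a concatenated-SNP tree is undefined for them, and keeping them deletes
# every crop/wild diagnostic site from the matrix.

library(feralscan)

gm <- read_vcf("results/cohort/cohort.vcf")
pm <- read_population_map("results/cohort/popmap.tsv")
grp <- function(g) pm$sample[pm$group == g]

keep <- pm$sample[pm$group != "weed_f1"]
gmt <- select_tree_sites(subset_geno(gm, samples = keep))
cat("tree sites (homozygous, complete):", n_sites(gmt), "\n")

boot <- bootstrap_support(gmt, B = 100, seed = 17)
rooted <- root_with_outgroup(boot, grp("outgroup"))
write_newick(rooted, "results/cohort_nj.nwk")

cs <- clade_support(rooted, grp("crop"), boot = boot)
in_clade <- function(g) sum(grp(g) %in% cs$tips)
cat(sprintf("smallest clade containing the crop: %d tips, bootstrap %d%%\n",
            length(cs$tips), round(cs$support)))
cat(sprintf("  de-domesticated weeds inside: %d/%d\n",
            in_clade("weed_dd"), length(grp("weed_dd"))))
cat(sprintf("  introgressed weeds inside:    %d/%d\n",
            in_clade("weed_ix"), length(grp("weed_ix"))))
cat(sprintf("  wild accessions inside:       %d/%d\n",
            in_clade("wild"), length(grp("wild"))))
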