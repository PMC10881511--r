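#!/usr/bin/env Rscript
# Stage 3 — private-SNP ancestry classification and chromosome painting.
#
# Classifies every SNP as crop-specific / wild-specific / shared /
# uninformative from the crop and wild reference panels, computes windowed and
# genome-wide crop:wild private-allele ratios per weed strain, paints each
# weed's chromosomes, writes wild-like blocks as BED, and scores the painting
# against the simulator's truth tracts. A diagnostic-locus table is genotyped
# at wild-specific sites inside known tracts.

library(feralscan)

gm <- read_vcf("results/cohort/cohort.vcf")
pm <- read_population_map("results/cohort/popmap.tsv")
grp <- function(g) pm$sample[pm$group == g]
params <- jsonlite::read_json("results/cohort/truth_params.json")
w <- make_windows(unlist(params$contig_lengths), 1e5)
truth <- read_bed("results/cohort/truth_tracts.bed")
truth$sample <- sub("\\|.*", "", truth$name)
truth$origin <- sub(".*\\|", "", truth$name)

cls <- classify_private_snps(gm, grp("crop"), grp("wild"))
write.table(cls, "results/site_classes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("site classes:\n"); print(table(cls$class))

tot <- sample_private_totals(cls, gm, pm$sample[pm$role == "weed"])
tot$group <- pm$group[match(tot$sample, pm$sample)]
write.table(tot, "results/private_totals.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("median crop:wild private-allele ratio by strain:\n")
print(tapply(tot$ratio, tot$group, median))

jac <- numeric(0)
for (s in grp("weed_ix")) {
  track <- paint_chromosomes(cls, gm, s, w)
  blocks <- painting_blocks(track, "wild_like")
  if (nrow(blocks))
    write_bed(blocks[, c("chrom", "start", "end")],
              sprintf("results/painting_%s.bed", s))
  tt <- truth[truth$sample == s & truth$origin == "wild",
              c("chrom", "start", "end")]
  jac[s] <- interval_jaccard(blocks, tt)
}
cat(sprintf("painting vs truth tracts: median Jaccard %.3f over %d weeds\n",
            median(jac), length(jac)))

# diagnostic loci: one wild-specific SNP inside a known tract per weed
ws <- which(cls$class == "wild_specific")
pick <- ws[seq(1, length(ws), length.out = 5)]
loci <- data.frame(gene = sprintf("locus%02d", seq_along(pick)),
                   chrom = cls$chrom[pick], pos = cls$pos[pick],
                   crop_allele = cls$ref[pick], wild_allele = cls$alt[pick])
calls <- genotype_diagnostic_loci(gm, loci)
calls$group <- pm$group[match(calls$sample, pm$sample)]
write.table(calls, "results/diagnostic_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("diagnostic wild-allele carriage by strain (fraction wild or het):\n")
print(round(tapply(calls$call %in% c("wild", "het"), calls$group, mean), 3))
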