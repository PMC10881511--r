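#!/usr/bin/env Rscript
# Stage 6 — candidate-window overlap across weed strains and gene intersection.
#
# Intersects the LNDR candidate windows of the two weed strains (stage 2) and
# annotates shared candidate regions with genes from a GFF3. The gene
# annotation here is synthetic (regular 30-kb gene models tiling the
# simulated contigs) since the cohort itself is simulated.

library(feralscan)

params <- jsonlite::read_json("results/cohort/truth_params.json")
lens <- unlist(params$contig_lengths)

sets <- list(weed_dd = read_bed("results/lndr_candidates_weed_dd.bed"),
             weed_ix = read_bed("results/lndr_candidates_weed_ix.bed"))
shared <- overlap_candidates(sets, min_strains = 2)
write.table(shared, "results/shared_windows.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("candidate windows: %d (dd), %d (ix); shared by both: %d\n",
            nrow(sets$weed_dd), nrow(sets$weed_ix), nrow(shared)))

# synthetic gene models: 30-kb genes every 40 kb (written/read as GFF3)
gff <- "results/synthetic_genes.gff3"
lines <- "##gff-version 3"
for (ch in names(lens)) {
  starts <- seq(0, lens[[ch]] - 4e4, by = 4e4)
  lines <- c(lines, sprintf("%s\tsim\tgene\t%d\t%d\t.\t+\t.\tID=%s_g%04d",
                            ch, starts + 1, starts + 3e4, ch,
                            seq_along(starts)))
}
writeLines(lines, gff)
genes <- read_gff3_genes(gff)

union_cand <- overlap_candidates(sets, min_strains = 1)
hits <- genes_in_regions(union_cand[, c("chrom", "start", "end")], genes)
write.table(hits, "results/candidate_genes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("genes overlapping any candidate window: %d of %d\n",
            nrow(hits), nrow(genes)))
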