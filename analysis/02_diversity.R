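#!/usr/bin/env Rscript
# Stage 2 — windowed diversity, heterozygosity and differentiation scans.
#
# Reads the stage-1 cohort back through the VCF path (exercising the I/O
# boundary), then computes per-window pi and Watterson's theta for each group,
# per-individual heterozygosity rates, crop-vs-wild F_ST, and the
# pi_crop/pi_weed (LNDR) selection scan per weed strain; top-5% windows are
# written as candidate BEDs.

library(feralscan)

gm <- read_vcf("results/cohort/cohort.vcf")
pm <- read_population_map("results/cohort/popmap.tsv")
grp <- function(g) pm$sample[pm$group == g]
params <- jsonlite::read_json("results/cohort/truth_params.json")
lens <- unlist(params$contig_lengths)
w <- make_windows(lens, 1e5)

tab <- w
for (g in c("wild", "crop", "weed_dd", "weed_ix")) {
  tab[[paste0("pi_", g)]] <- window_pi(gm, grp(g), w)$pi
  tab[[paste0("theta_", g)]] <- window_theta_w(gm, grp(g), w)$theta_w
}
tab$fst_crop_wild <- wc_fst(gm, grp("crop"), grp("wild"), w)$fst
write.table(tab, "results/windows.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("mean pi: wild %.4g, crop %.4g, weed_dd %.4g  (crop/wild = %.2f)\n",
            mean(tab$pi_wild), mean(tab$pi_crop), mean(tab$pi_weed_dd),
            mean(tab$pi_crop) / mean(tab$pi_wild)))
cat(sprintf("mean crop-wild F_ST: %.3f\n", mean(tab$fst_crop_wild, na.rm = TRUE)))

het <- heterozygosity_rate(gm)
het$group <- pm$group[match(het$sample, pm$sample)]
write.table(het, "results/het_per_sample.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
med <- tapply(het$het_rate, het$group, median, na.rm = TRUE)
cat("median het rate by group:\n")
print(round(med, 4))

for (g in c("weed_dd", "weed_ix")) {
  scan <- pi_ratio_scan(gm, grp("crop"), grp(g), w)
  write.table(scan, sprintf("results/lndr_scan_%s.tsv", g), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cand <- scan[scan$is_candidate, c("chrom", "start", "end")]
  write_bed(cand, sprintf("results/lndr_candidates_%s.bed", g))
  cat(sprintf("%s: %d eligible windows, %d LNDR candidates\n",
              g, sum(scan$eligible), nrow(cand)))
}
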