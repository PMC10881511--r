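small_cfg <- function(seed = 1, ...) {
  args <- list(n_wild = 8, n_crop = 8,
               n_weed = c(dedomesticated = 4, introgressed = 4, f1 = 2),
               n_outgroup = 1, contig_lengths = c(chr1 = 1e6),
               sweep_intervals = NULL, seed = seed)
  do.call(scenario_config, utils::modifyList(args, list(...)))
}

test_that("scenario validation rejects bad configurations", {
  expect_error(small_cfg(tract_length_mean = 5e3), "10 kb")
  expect_error(small_cfg(crop_bottleneck_k = 100), "haplotype count")
  expect_error(small_cfg(introgression_fraction = 1.2), "fraction")
  expect_error(small_cfg(sweep_intervals = data.frame(
    chrom = "chr1", start = c(0, 5e5), end = c(6e5, 9e5),
    group = "weed_dd")), "overlapping")
})

test_that("wild panel has no sites at theta 0 and is seed-deterministic", {
  cfg0 <- small_cfg(theta_wild = 0)
  pool <- simulate_wild_panel(cfg0)
  expect_equal(length(pool$contigs$chr1$pos), 0L)
  cfg <- small_cfg(seed = 33)
  p1 <- simulate_wild_panel(cfg)
  p2 <- simulate_wild_panel(cfg)
  expect_identical(p1, p2)
})

test_that("a full cohort is byte-identical under the same seed", {
  cfg <- small_cfg(seed = 12)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$gm, c2$gm)
  expect_identical(c1$truth, c2$truth)
})

test_that("emit_cohort writes loadable, reproducible fixture files", {
  cfg <- small_cfg(seed = 5, contig_lengths = c(chr1 = 2e5))
  d1 <- tempfile(); d2 <- tempfile()
  co <- emit_cohort(cfg, d1)
  emit_cohort(cfg, d2)
  files <- attr(co, "files")
  expect_true(all(file.exists(files[c("vcf", "popmap", "tracts", "params")])))
  for (f in names(files)) {
    if (!file.exists(files[[f]])) next
    expect_identical(readLines(files[[f]]),
                     readLines(file.path(d2, basename(files[[f]]))))
  }
  gm <- read_vcf(files["vcf"])
  expect_gt(n_sites(gm), 0)
  expect_identical(gm$geno, co$gm$geno)
  pm <- read_population_map(files["popmap"])
  expect_equal(sort(unique(pm$group)),
               sort(unique(co$popmap$group)))
})

test_that("a k = 1 bottleneck gives identical, fully homozygous crop", {
  cfg <- small_cfg(crop_bottleneck_k = 1, theta_crop_mut = 0,
                   contig_lengths = c(chr1 = 2e5))
  pool <- simulate_wild_panel(cfg)
  crop <- simulate_crop(pool, cfg)
  H <- crop$contigs$chr1$H
  expect_true(all(H == rep(H[1, ], each = nrow(H))))
  gm <- haps_to_genotypes(crop, sprintf("c%d", 1:8))
  w <- make_windows(cfg$contig_lengths, 2e5)
  expect_equal(window_pi(gm, gm$sample_ids, w)$pi, 0)
})

test_that("with no selfing, crop heterozygosity matches the Hardy-Weinberg
           expectation from founder frequencies", {
  cfg <- small_cfg(seed = 8, selfing_generations = 0, n_crop = 40,
                   bottleneck_fixation = 0, theta_crop_mut = 0,
                   contig_lengths = c(chr1 = 5e5))
  pool <- simulate_wild_panel(cfg)
  crop <- simulate_crop(pool, cfg)
  HF <- attr(crop, "founders")$contigs$chr1$H
  f <- colMeans(HF)
  exp_het <- sum(2 * f * (1 - f))           # expected het sites per individual
  gm <- haps_to_genotypes(crop, sprintf("c%d", 1:40))
  obs <- rowSums(gm$geno == 1L)
  se <- stats::sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - exp_het), 3 * se + 1e-9)
})

test_that("crop diversity falls below wild diversity across seeds", {
  ok <- vapply(1:6, function(s) {
    co <- simulate_cohort(small_cfg(seed = 400 + s,
                                    contig_lengths = c(chr1 = 5e5)))
    w <- make_windows(c(chr1 = 5e5), 1e5)
    mean(window_pi(co$gm, cohort_group(co, "crop"), w)$pi) <
      mean(window_pi(co$gm, cohort_group(co, "wild"), w)$pi)
  }, logical(1))
  expect_true(all(ok))
})

test_that("F1 weeds are heterozygous wherever their parents' gametes differ", {
  cfg <- small_cfg(seed = 3, contig_lengths = c(chr1 = 2e5))
  co <- simulate_cohort(cfg)
  f1 <- cohort_group(co, "weed_f1")
  het <- heterozygosity_rate(co$gm, f1)
  expect_true(all(het$het_rate > 0.3))
  selfed <- heterozygosity_rate(co$gm, c(cohort_group(co, "weed_dd"),
                                         cohort_group(co, "weed_ix")))
  expect_true(all(het$het_rate >= 10 * stats::median(selfed$het_rate),
                  na.rm = TRUE))
})

test_that("introgression_fraction 0 yields all-crop truth tracts", {
  cfg <- small_cfg(seed = 4, introgression_fraction = 0,
                   contig_lengths = c(chr1 = 2e5))
  co <- simulate_cohort(cfg)
  tr <- co$truth$tracts
  ix <- tr[grepl("weed_ix", tr$sample), ]
  expect_true(all(ix$origin == "crop"))
})

test_that("realized wild-tract fraction is close to the configured value", {
  cfg <- small_cfg(seed = 6, n_weed = c(introgressed = 20),
                   contig_lengths = c(chr1 = 4e6))
  co <- simulate_cohort(cfg)
  tr <- co$truth$tracts
  wt <- tr[tr$origin == "wild", ]
  frac <- sum(wt$end - wt$start) / (20 * 4e6)
  expect_lt(abs(frac - 0.2) / 0.2, 0.30)
})

test_that("truth tracts tile the genome without overlap for every selfed weed", {
  co <- simulate_cohort(small_cfg(seed = 7, contig_lengths = c(chr1 = 3e5)))
  tr <- co$truth$tracts
  for (s in unique(tr$sample)) {
    t <- tr[tr$sample == s, ]
    t <- t[order(t$chrom, t$start), ]
    expect_equal(sum(t$end - t$start), 3e5)
    for (ch in unique(t$chrom)) {
      tc <- t[t$chrom == ch, ]
      expect_true(all(tc$start[-1] >= tc$end[-nrow(tc)]))
    }
  }
  expect_true(all(tr$origin %in% c("crop", "wild")))
})

test_that("inject_sweep wipes core diversity, spares distant sites exactly", {
  cfg <- small_cfg(seed = 9, n_wild = 10, contig_lengths = c(chr1 = 1e6))
  pool <- simulate_wild_panel(cfg)
  gm_before <- haps_to_genotypes(pool, sprintf("w%d", 1:10))
  swept <- inject_sweep(pool, "chr1", 4e5, 6e5, cfg$theta_wild)
  gm_after <- haps_to_genotypes(swept, sprintf("w%d", 1:10))
  w <- make_windows(c(chr1 = 1e6), 1e5)
  pi_b <- window_pi(gm_before, gm_before$sample_ids, w)$pi
  pi_a <- window_pi(gm_after, gm_after$sample_ids, w)$pi
  # window fully inside the core
  expect_lt(pi_a[5], 0.05 * pi_b[5])
  expect_gt(pi_a[5], 0)           # singleton sprinkle retained
  # windows fully outside core + 50 kb flank are untouched bit-exactly
  expect_identical(pi_a[c(1, 2, 3, 9, 10)], pi_b[c(1, 2, 3, 9, 10)])
  expect_error(inject_sweep(pool, "chr1", 9e5, 2e6, cfg$theta_wild),
               "outside")
  # truth BED round-trips
  st <- attr(swept, "sweep_truth")
  bed <- tempfile(fileext = ".bed")
  write_bed(st, bed)
  rt <- read_bed(bed)
  expect_equal(rt$chrom, st$chrom)
  expect_equal(as.numeric(rt$start), as.numeric(st$start))
  expect_equal(as.numeric(rt$end), as.numeric(st$end))
})

test_that("wild-specific alleles of introgressed weeds concentrate in truth tracts", {
  co <- default_cohort(1)
  grp <- function(g) cohort_group(co, g)
  cls <- classify_private_snps(co$gm, grp("crop"), grp("wild"))
  ws <- cls$class == "wild_specific"
  tr <- co$truth$tracts
  frac_in <- vapply(grp("weed_ix"), function(s) {
    g <- co$gm$geno[s, ]
    g[g < 0] <- 0L
    copies <- g * ws
    wt <- tr[tr$sample == s & tr$origin == "wild", ]
    if (sum(copies) == 0) return(NA_real_)
    inside <- rep(FALSE, n_sites(co$gm))
    for (t in seq_len(nrow(wt)))
      inside <- inside | (co$gm$sites$chrom == wt$chrom[t] &
                            co$gm$sites$pos - 1 >= wt$start[t] &
                            co$gm$sites$pos - 1 < wt$end[t])
    sum(copies[inside]) / sum(copies)
  }, numeric(1))
  expect_gte(mean(frac_in, na.rm = TRUE), 0.9)
})
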