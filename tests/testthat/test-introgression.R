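make_gm <- function(geno, pos = seq_len(ncol(geno)) * 10L, chrom = "chr1") {
  geno_matrix(geno, sprintf("s%02d", seq_len(nrow(geno))),
              data.frame(chrom = chrom, pos = as.integer(pos),
                         ref = "A", alt = "T"))
}

test_that("private-SNP classes follow the presence rules", {
  # crop s01-s02, wild s03-s04
  geno <- rbind(c(2L, 1L, 0L), c(1L, 1L, 0L),
                c(0L, 2L, 0L), c(0L, 2L, 1L))
  gm <- make_gm(geno)
  cls <- classify_private_snps(gm, c("s01", "s02"), c("s03", "s04"))
  expect_equal(as.character(cls$class),
               c("crop_specific", "shared", "wild_specific"))
  expect_error(classify_private_snps(gm, c("s01", "s02"), c("s02", "s03")),
               "overlap")
})

test_that("classification matches a truth-table oracle over all complete columns", {
  cols <- as.matrix(expand.grid(rep(list(0:2), 4)))  # 81 complete columns
  gm <- make_gm(t(cols))
  crop <- c("s01", "s02"); wild <- c("s03", "s04")
  cls <- classify_private_snps(gm, crop, wild, min_carriers = 1,
                               max_missing_frac = 0)
  oracle <- apply(cols, 1, function(cc) {
    jc <- sum(cc[1:2]); jw <- sum(cc[3:4])
    if (jc > 0 && jw == 0) "crop_specific"
    else if (jw > 0 && jc == 0) "wild_specific"
    else if (jc > 0 && jw > 0) "shared"
    else "uninformative"
  })
  expect_equal(as.character(cls$class), unname(oracle))
  # the four labels partition the sites
  expect_equal(sum(table(cls$class)), n_sites(gm))
})

test_that("swapping the panels swaps crop and wild labels exactly", {
  gm <- rand_gm(8, 120, miss = 0.05, seed = 21)
  a <- classify_private_snps(gm, gm$sample_ids[1:4], gm$sample_ids[5:8])
  b <- classify_private_snps(gm, gm$sample_ids[5:8], gm$sample_ids[1:4])
  map <- c(crop_specific = "wild_specific", wild_specific = "crop_specific",
           shared = "shared", uninformative = "uninformative")
  expect_equal(unname(map[as.character(a$class)]), as.character(b$class))
})

test_that("windowed private ratio counts copies and guards zeros", {
  # 3 crop-specific sites (2 copies each target) and 1 wild-specific (3 copies)
  geno <- rbind(c(2L, 2L, 2L, 0L),   # crop panel
                c(0L, 0L, 0L, 2L),   # wild panel
                c(2L, 2L, 2L, 1L),   # target 1: 6 crop copies, 1 wild
                c(0L, 0L, 0L, 2L))   # target 2: 0 crop, 2 wild
  gm <- make_gm(geno)
  cls <- classify_private_snps(gm, "s01", "s02")
  w <- make_windows(c(chr1 = 100), 100)
  r <- window_private_ratio(cls, gm, c("s03", "s04"), w)
  expect_equal(r$crop_copies, 6)
  expect_equal(r$wild_copies, 3)
  expect_equal(r$ratio, 2)
  expect_equal(r$log_ratio, 1)   # log2
  r2 <- window_private_ratio(cls, gm, "s03", w, count_sites = TRUE)
  expect_equal(r2$crop_copies, 3)
  # zero wild copies -> undefined flag
  r0 <- window_private_ratio(cls, gm, "s01", w)
  expect_false(r0$defined)
  expect_true(is.na(r0$log_ratio))
})

test_that("painting calls follow thresholds and min_informative", {
  # 20 wild-specific copies, 0 crop in window 1; 4 informative in window 2
  crop_panel <- c(rep(0L, 10), rep(2L, 2))
  wild_panel <- c(rep(2L, 10), rep(0L, 2))
  target <- c(rep(2L, 10), c(2L, 2L))
  gm <- make_gm(rbind(crop_panel, wild_panel, target),
                pos = c(1:10 * 10L, 101L, 151L))
  cls <- classify_private_snps(gm, "s01", "s02")
  w <- make_windows(c(chr1 = 200), 100)
  tr <- paint_chromosomes(cls, gm, "s03", w)
  expect_equal(as.character(tr$call), c("wild_like", "undetermined"))
  expect_equal(tr$n_wild_copies, c(20, 0))
  expect_equal(tr$n_crop_copies, c(0, 4))
  blocks <- painting_blocks(tr)
  expect_equal(nrow(blocks), 2L)
  expect_error(paint_chromosomes(cls, gm, "nope", w), "unknown")
})

test_that("painting block merge joins adjacent same-call windows", {
  w <- make_windows(c(chr1 = 400), 100)
  tr <- w
  tr$call <- factor(c("wild_like", "wild_like", "crop_like", "wild_like"),
                    levels = c("crop_like", "wild_like", "mixed", "undetermined"))
  class(tr) <- c("painting_track", class(tr))
  b <- painting_blocks(tr, "wild_like")
  expect_equal(b$start, c(0, 300))
  expect_equal(b$end, c(200, 400))
})

test_that("diagnostic locus genotyping respects allele orientation", {
  gm <- make_gm(rbind(c(0L, 2L), c(2L, 0L), c(1L, -1L)),
                pos = c(100L, 200L))
  loci <- data.frame(gene = c("g1", "g2", "g3"),
                     chrom = "chr1", pos = c(100L, 200L, 999L),
                     crop_allele = c("A", "T", "A"),
                     wild_allele = c("T", "A", "T"))
  calls <- genotype_diagnostic_loci(gm, loci)
  g1 <- calls[calls$gene == "g1", ]
  expect_equal(g1$call, c("crop", "wild", "het"))
  g2 <- calls[calls$gene == "g2", ]  # crop allele is the alt here
  expect_equal(g2$call, c("crop", "wild", "missing"))
  expect_true(all(calls$call[calls$gene == "g3"] == "absent"))
  expect_error(genotype_diagnostic_loci(gm, loci[c(1, 1), ]), "duplicate")
  loci_bad <- loci[1, ]; loci_bad$crop_allele <- "G"
  expect_warning(out <- genotype_diagnostic_loci(gm, loci_bad), "match")
  expect_true(all(out$call == "absent"))
})

test_that("diagnostic calls inside simulated wild tracts match tract truth", {
  co <- default_cohort(1)
  grp <- function(g) cohort_group(co, g)
  cls <- classify_private_snps(co$gm, grp("crop"), grp("wild"))
  wild_sites <- which(cls$class == "wild_specific")
  tr <- co$truth$tracts
  checks <- 0; hits <- 0
  for (s in grp("weed_ix")) {
    wt <- tr[tr$sample == s & tr$origin == "wild", ]
    if (!nrow(wt)) next
    for (t in seq_len(min(nrow(wt), 2))) {
      inside <- wild_sites[cls$chrom[wild_sites] == wt$chrom[t] &
                             cls$pos[wild_sites] - 1 >= wt$start[t] &
                             cls$pos[wild_sites] - 1 < wt$end[t]]
      # a diagnostic locus = a wild-specific site the sample actually carries
      inside <- inside[co$gm$geno[s, inside] > 0]
      if (!length(inside)) next
      i <- inside[ceiling(length(inside) / 2)]
      loci <- data.frame(gene = "d", chrom = cls$chrom[i], pos = cls$pos[i],
                         crop_allele = cls$ref[i], wild_allele = cls$alt[i])
      call <- genotype_diagnostic_loci(co$gm, loci)
      call <- call$call[call$sample == s]
      checks <- checks + 1
      if (call %in% c("wild", "het")) hits <- hits + 1
    }
  }
  expect_gt(checks, 5)
  expect_gte(hits / checks, 0.95)
})
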