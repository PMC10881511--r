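test_that("site_pi equals the mean pairwise allele difference", {
  expect_equal(site_pi(0, 4), 0)
  expect_equal(site_pi(2, 4), 2 / 3)   # 6 pairs, 4 differing
  expect_equal(site_pi(1, 2), 1)
  expect_true(is.na(site_pi(0, 1)))
})

test_that("window_pi matches its single-site example and the empty case", {
  gm <- geno_matrix(matrix(c(1L, 1L), 2, 1), c("a", "b"),
                    data.frame(chrom = "chr1", pos = 50L, ref = "A", alt = "T"))
  w <- make_windows(c(chr1 = 2e5), 1e5)
  res <- window_pi(gm, c("a", "b"), w)
  expect_equal(res$pi[1], (2 / 3) / 1e5)  # j = 2, n = 4
  expect_equal(res$pi[2], 0)
  expect_equal(res$n_snps, c(1L, 0L))
  expect_error(window_pi(gm, character(0), w), "empty")
})

test_that("window_theta_w matches the harmonic-sum example", {
  # 3 segregating sites among 2 samples (n = 4 alleles) in a 100-bp window
  gm <- geno_matrix(matrix(c(0L, 1L, 1L, 0L, 2L, 0L), 2, 3), c("a", "b"),
                    data.frame(chrom = "c", pos = c(10L, 40L, 70L),
                               ref = "A", alt = "T"))
  w <- make_windows(c(c = 100), 100)
  res <- window_theta_w(gm, c("a", "b"), w)
  expect_equal(res$theta_w, 3 / ((1 + 1 / 2 + 1 / 3) * 100), tolerance = 1e-9)
  # no segregating site -> 0
  gm0 <- geno_matrix(matrix(2L, 2, 1), c("a", "b"),
                     data.frame(chrom = "c", pos = 5L, ref = "A", alt = "T"))
  expect_equal(window_theta_w(gm0, c("a", "b"), w)$theta_w, 0)
})

test_that("windowed pi and theta match brute-force oracles on random matrices", {
  for (s in 1:6) {
    gm <- rand_gm(6, 60, miss = 0.15, seed = s, L = 3e4)
    w <- make_windows(c(chr1 = 3e4), 1e4)
    smp <- gm$sample_ids
    expect_equal(window_pi(gm, smp, w)$pi, brute_window_pi(gm, smp, w),
                 tolerance = 1e-12)
    expect_equal(window_theta_w(gm, smp, w)$theta_w,
                 brute_window_theta(gm, smp, w), tolerance = 1e-12)
  }
})

test_that("heterozygosity_rate counts het among variant sites", {
  gm <- geno_matrix(matrix(c(1L, 2L, 2L, 2L, 0L, -1L), 1, 6), "a",
                    data.frame(chrom = "c", pos = 1:6 * 10L, ref = "A", alt = "T"))
  hr <- heterozygosity_rate(gm, "a")
  expect_equal(hr$n_variant_sites, 4L)
  expect_equal(hr$het_rate, 0.25)
  gm2 <- geno_matrix(matrix(2L, 1, 3), "a",
                     data.frame(chrom = "c", pos = 1:3 * 10L, ref = "A", alt = "T"))
  expect_equal(heterozygosity_rate(gm2)$het_rate, 0)
  expect_error(heterozygosity_rate(gm, "nope"), "unknown")
})

test_that("wc_fst is 1 at complete fixation and matches the WC84 oracle", {
  gm <- geno_matrix(rbind(matrix(0L, 3, 4), matrix(2L, 3, 4)),
                    sprintf("s%d", 1:6),
                    data.frame(chrom = "c", pos = 1:4 * 10L, ref = "A", alt = "T"))
  w <- make_windows(c(c = 100), 100)
  res <- wc_fst(gm, sprintf("s%d", 1:3), sprintf("s%d", 4:6), w)
  expect_equal(res$fst, 1)
  # identical genotype columns in both pops: small/negative value, equal to oracle
  gm2 <- geno_matrix(rbind(matrix(c(0L, 1L, 2L, 1L), 2, 4, byrow = TRUE),
                           matrix(c(0L, 1L, 2L, 1L), 2, 4, byrow = TRUE)),
                     sprintf("s%d", 1:4),
                     data.frame(chrom = "c", pos = 1:4 * 10L, ref = "A", alt = "T"))
  res2 <- wc_fst(gm2, sprintf("s%d", 1:2), sprintf("s%d", 3:4), w)
  oracle2 <- brute_window_fst(gm2, sprintf("s%d", 1:2), sprintf("s%d", 3:4), w)
  expect_true(res2$fst <= 0)
  expect_equal(res2$fst, oracle2, tolerance = 1e-12)
  expect_error(wc_fst(gm2, character(0), "s3", w), "0 samples")
})

test_that("wc_fst matches the brute-force oracle on random matrices", {
  for (s in 1:6) {
    gm <- rand_gm(10, 60, miss = 0.1, seed = 100 + s, L = 3e4)
    w <- make_windows(c(chr1 = 3e4), 1e4)
    popA <- gm$sample_ids[1:5]; popB <- gm$sample_ids[6:10]
    expect_equal(wc_fst(gm, popA, popB, w)$fst,
                 brute_window_fst(gm, popA, popB, w), tolerance = 1e-12)
  }
})

test_that("statistics are invariant to sample order and zero iff no segregation", {
  gm <- rand_gm(8, 80, miss = 0.1, seed = 9, L = 4e4)
  w <- make_windows(c(chr1 = 4e4), 1e4)
  smp <- gm$sample_ids
  perm <- rev(smp)
  expect_equal(window_pi(gm, smp, w)$pi, window_pi(gm, perm, w)$pi)
  expect_equal(window_theta_w(gm, smp, w)$theta_w,
               window_theta_w(gm, perm, w)$theta_w)
  expect_equal(wc_fst(gm, smp[1:4], smp[5:8], w)$fst,
               wc_fst(gm, rev(smp[1:4]), rev(smp[5:8]), w)$fst)
  pi <- window_pi(gm, smp, w)
  th <- window_theta_w(gm, smp, w)
  expect_equal(pi$pi == 0, th$theta_w == 0)
})

test_that("pi_ratio_scan flags the top fraction with tie handling", {
  # 100 eligible windows with distinct ratios -> exactly 5 candidates
  set.seed(2)
  n <- 100
  w <- make_windows(c(chr1 = n * 1e5), 1e5)
  pos <- as.integer(seq(5e4, n * 1e5 - 5e4, length.out = 20 * n))
  geno_crop <- matrix(1L, 4, length(pos))
  # weed diversity varies by window: higher code mix -> lower ratio
  geno_weed <- matrix(rep(c(0L, 1L, 1L, 2L), length(pos) / 4 * 4)[
    seq_len(4 * length(pos))], 4, length(pos))
  gm <- geno_matrix(rbind(geno_crop, geno_weed),
                    c(sprintf("c%d", 1:4), sprintf("w%d", 1:4)),
                    data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "T"))
  res <- pi_ratio_scan(gm, sprintf("c%d", 1:4), sprintf("w%d", 1:4), w,
                       top_frac = 0.05, min_snps = 10)
  expect_equal(sum(res$eligible), 100)
  # all ratios tie here, so all eligible windows are candidates (tie rule)
  expect_equal(sum(res$is_candidate), 100)
  expect_error(pi_ratio_scan(gm, "c1", "w1", w, top_frac = 1.5), "top_frac")
})

test_that("pi_ratio_scan computes ratios and guards division", {
  gm <- rand_gm(8, 400, miss = 0, seed = 11, L = 4e5)
  w <- make_windows(c(chr1 = 4e5), 1e5)
  crop <- gm$sample_ids[1:4]; weed <- gm$sample_ids[5:8]
  res <- pi_ratio_scan(gm, crop, weed, w, min_snps = 1)
  pc <- window_pi(gm, crop, w)$pi
  pw <- window_pi(gm, weed, w)$pi
  expect_equal(res$pi_ratio[res$eligible], (pc / pw)[res$eligible])
  k <- ceiling(0.05 * sum(res$eligible))
  expect_gte(sum(res$is_candidate), k)
  # a window with pi_weed = 0 is ineligible
  gm$geno[5:8, window_of_sites_idx <- which(gm$sites$pos <= 1e5)] <- 0L
  res0 <- pi_ratio_scan(gm, crop, weed, w, min_snps = 1)
  expect_false(res0$eligible[1])
  expect_true(is.na(res0$pi_ratio[1]))
})
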