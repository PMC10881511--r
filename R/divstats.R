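# Windowed diversity, heterozygosity, differentiation and pi-ratio scans.
# Window denominators use the full window length (all sites assumed callable),
# the convention of standard VCF-based window scans.

#' Per-site pairwise diversity
#'
#' Unbiased per-site heterozygosity `2 j (n - j) / (n (n - 1))`: the mean
#' pairwise difference over all C(n, 2) allele pairs.
#'
#' @param j Alt-allele copy count(s) among non-missing calls.
#' @param n Total non-missing allele count(s) (2 x non-missing diploids).
#' @return Numeric vector; `NA` where `n < 2` (site unusable).
#' @export
site_pi <- function(j, n) {
  out <- ifelse(n >= 2, 2 * j * (n - j) / (n * (n - 1)), NA_real_)
  out
}

# shared per-window scaffold: returns window table + site->window index + counts
window_site_stats <- function(gm, samples, windows) {
  ac <- site_allele_counts(gm, samples)
  widx <- window_of_sites(gm, windows)
  seg <- ac$j > 0L & ac$j < ac$n & ac$n >= 2L
  list(ac = ac, widx = widx, seg = seg)
}

sum_by_window <- function(x, widx, n_windows) {
  out <- numeric(n_windows)
  ok <- !is.na(widx) & !is.na(x)
  if (any(ok)) {
    s <- rowsum(x[ok], widx[ok])
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Windowed nucleotide diversity (pi)
#'
#' Per window: sum of [site_pi()] over SNPs in the window divided by the
#' window length in bp. `n_snps` counts sites segregating within the selected
#' samples.
#'
#' @param gm A [geno_matrix()].
#' @param samples Character vector of sample ids.
#' @param windows Window table from [make_windows()].
#' @return `windows` with columns `n_snps` and `pi` appended.
#' @export
window_pi <- function(gm, samples, windows) {
  if (length(samples) == 0) stop("empty sample set")
  st <- window_site_stats(gm, samples, windows)
  sp <- site_pi(st$ac$j, st$ac$n)
  nw <- nrow(windows)
  windows$n_snps <- as.integer(sum_by_window(as.numeric(st$seg), st$widx, nw))
  windows$pi <- sum_by_window(ifelse(is.na(sp), 0, sp), st$widx, nw) /
    (windows$end - windows$start)
  windows
}

#' Windowed Watterson estimator (theta_W)
#'
#' Per window: `S / (a_{n-1} * L)` with `S` the count of segregating sites
#' among the selected samples and `L` the window length. Because missingness
#' makes the allele count vary by site, `a_{n-1}` uses the median allele count
#' over the window's segregating sites (windows with `S = 0` get 0).
#'
#' @inheritParams window_pi
#' @return `windows` with columns `n_snps` and `theta_w` appended.
#' @export
window_theta_w <- function(gm, samples, windows) {
  if (length(samples) == 0) stop("empty sample set")
  st <- window_site_stats(gm, samples, windows)
  nw <- nrow(windows)
  S <- sum_by_window(as.numeric(st$seg), st$widx, nw)
  theta <- numeric(nw)
  seg_w <- st$widx[st$seg & !is.na(st$widx)]
  seg_n <- st$ac$n[st$seg & !is.na(st$widx)]
  med_n <- tapply(seg_n, seg_w, stats::median)
  wid <- as.integer(names(med_n))
  a_n <- vapply(med_n, function(n) sum(1 / seq_len(max(1, round(n) - 1))), numeric(1))
  theta[wid] <- S[wid] / (a_n * (windows$end - windows$start)[wid])
  windows$n_snps <- as.integer(S)
  windows$theta_w <- theta
  windows
}

#' Per-individual heterozygosity rate
#'
#' The proportion of an individual's variant sites (non-missing genotypes
#' carrying at least one alt allele, i.e. codes 1 or 2) that are heterozygous.
#' Elevated rates flag recent outcrossing (e.g. F1 hybrids) in predominantly
#' selfing populations.
#'
#' @param gm A [geno_matrix()].
#' @param samples Sample ids (default: all).
#' @return data.frame with `sample`, `n_variant_sites`, `n_het`, `het_rate`
#'   (`NA` when the individual has no variant site).
#' @export
heterozygosity_rate <- function(gm, samples = gm$sample_ids) {
  miss <- setdiff(samples, gm$sample_ids)
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  g <- gm$geno[samples, , drop = FALSE]
  n_var <- rowSums(g == 1L | g == 2L)
  n_het <- rowSums(g == 1L)
  data.frame(sample = samples,
             n_variant_sites = as.integer(n_var),
             n_het = as.integer(n_het),
             het_rate = ifelse(n_var > 0, n_het / n_var, NA_real_),
             row.names = NULL)
}

# Weir & Cockerham (1984) two-population variance components for one or more
# sites. Inputs are per-site vectors: n1, n2 = non-missing individuals,
# p1, p2 = alt allele frequencies, h1, h2 = observed het fractions.
wc_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  list(a = a, b = b, c = c)
}

#' Windowed Weir-Cockerham F_ST between two populations
#'
#' Per-site variance components a, b, c of the Weir & Cockerham (1984)
#' estimator are summed over usable sites in each window and the window value
#' is the ratio of sums `sum(a) / sum(a + b + c)`. Sites monomorphic across
#' both populations, or with fewer than one genotyped individual in either
#' population or three overall (the estimator needs `nbar > 1`), are skipped;
#' a window with no usable site is `NA`.
#'
#' @param gm A [geno_matrix()].
#' @param popA,popB Sample id vectors for the two populations.
#' @param windows Window table from [make_windows()].
#' @return `windows` with columns `n_sites_used` and `fst` appended.
#' @export
wc_fst <- function(gm, popA, popB, windows) {
  if (!length(popA) || !length(popB)) stop("population with 0 samples")
  acA <- site_allele_counts(gm, popA)
  acB <- site_allele_counts(gm, popB)
  n1 <- acA$n / 2; n2 <- acB$n / 2
  # WC84 needs nbar > 1: at least one individual per pop and three overall
  usable <- n1 >= 1 & n2 >= 1 & (n1 + n2) >= 3
  p1 <- ifelse(acA$n > 0, acA$j / acA$n, NA_real_)
  p2 <- ifelse(acB$n > 0, acB$j / acB$n, NA_real_)
  poly <- usable & !( (acA$j + acB$j) == 0 | (acA$j + acB$j) == (acA$n + acB$n) )
  h1 <- ifelse(n1 > 0, acA$n_het / n1, NA_real_)
  h2 <- ifelse(n2 > 0, acB$n_het / n2, NA_real_)
  comp <- wc_components(n1, n2, p1, p2, h1, h2)
  widx <- window_of_sites(gm, windows)
  nw <- nrow(windows)
  use <- poly & !is.na(widx)
  sa <- sum_by_window(ifelse(poly, comp$a, 0), widx, nw)
  sabc <- sum_by_window(ifelse(poly, comp$a + comp$b + comp$c, 0), widx, nw)
  nuse <- sum_by_window(as.numeric(poly), widx, nw)
  windows$n_sites_used <- as.integer(nuse)
  windows$fst <- ifelse(nuse > 0 & sabc != 0, sa / sabc, NA_real_)
  windows
}

#' Pi-ratio (LNDR) selection scan
#'
#' Computes per-window `pi_crop / pi_weed` and flags the top fraction of
#' eligible windows as low-nucleotide-diversity-region (LNDR) candidates:
#' diversity wiped out in the weed relative to its crop ancestor is the
#' signature of a recent selective sweep in the weed lineage. A window is
#' eligible when both groups have at least `min_snps` segregating sites in it
#' and `pi_weed > 0`. Candidates are the top `ceiling(top_frac * N_eligible)`
#' windows by ratio; ties at the threshold are all included.
#'
#' @param gm A [geno_matrix()].
#' @param crop_samples,weed_samples Sample id vectors.
#' @param windows Window table from [make_windows()].
#' @param top_frac Candidate fraction (default 0.05, the top 5% of windows).
#' @param min_snps Minimum segregating sites per window per group (default 10).
#' @return `windows` with `pi_crop`, `pi_weed`, `n_snps_crop`, `n_snps_weed`,
#'   `pi_ratio` (`NA` when ineligible), `eligible` and `is_candidate` appended.
#' @export
pi_ratio_scan <- function(gm, crop_samples, weed_samples, windows,
                          top_frac = 0.05, min_snps = 10) {
  if (top_frac <= 0 || top_frac > 1) stop("top_frac must be in (0, 1]")
  if (!length(crop_samples) || !length(weed_samples)) stop("empty group")
  wc <- window_pi(gm, crop_samples, windows)
  ww <- window_pi(gm, weed_samples, windows)
  out <- windows
  out$pi_crop <- wc$pi
  out$pi_weed <- ww$pi
  out$n_snps_crop <- wc$n_snps
  out$n_snps_weed <- ww$n_snps
  out$eligible <- out$n_snps_crop >= min_snps & out$n_snps_weed >= min_snps &
    out$pi_weed > 0
  out$pi_ratio <- ifelse(out$eligible, out$pi_crop / out$pi_weed, NA_real_)
  out$is_candidate <- FALSE
  ne <- sum(out$eligible)
  if (ne > 0) {
    k <- ceiling(top_frac * ne)
    thr <- sort(out$pi_ratio[out$eligible], decreasing = TRUE)[k]
    out$is_candidate <- out$eligible & out$pi_ratio >= thr
  }
  out
}
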