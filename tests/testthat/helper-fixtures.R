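# Shared fixtures and independent brute-force oracles.

# random genotype matrix with controlled missingness
rand_gm <- function(n_samples = 6, n_sites = 50, miss = 0.1, seed = 1,
                    chroms = "chr1", L = 1e5) {
  set.seed(seed)
  pos <- sort(sample.int(L, n_sites))
  codes <- sample(c(-1L, 0L, 1L, 2L), n_samples * n_sites, replace = TRUE,
                  prob = c(miss, (1 - miss) / 2, (1 - miss) / 4, (1 - miss) / 4))
  ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  geno_matrix(matrix(codes, n_samples, n_sites),
              sprintf("s%02d", seq_len(n_samples)),
              data.frame(chrom = chroms, pos = pos, ref = ref, alt = alt))
}

# memoized default cohorts so acceptance blocks can share them
.cohort_cache <- new.env(parent = emptyenv())
default_cohort <- function(seed) {
  key <- paste0("seed", seed)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- simulate_cohort(scenario_config(seed = seed))
  .cohort_cache[[key]]
}
cohort_group <- function(co, g) co$popmap$sample[co$popmap$group == g]

# ---- brute-force oracles ---------------------------------------------------

# expand one genotype column into an allele vector (missing dropped)
expand_alleles <- function(codes) {
  out <- integer(0)
  for (g in codes) {
    if (g == 0L) out <- c(out, 0L, 0L)
    else if (g == 1L) out <- c(out, 0L, 1L)
    else if (g == 2L) out <- c(out, 1L, 1L)
  }
  out
}

# windowed pi by explicit loop over all allele pairs at each site
brute_window_pi <- function(gm, samples, windows) {
  g <- gm$geno[samples, , drop = FALSE]
  out <- numeric(nrow(windows))
  for (w in seq_len(nrow(windows))) {
    tot <- 0
    for (s in seq_len(ncol(g))) {
      if (gm$sites$chrom[s] != windows$chrom[w]) next
      p0 <- gm$sites$pos[s] - 1L
      if (p0 < windows$start[w] || p0 >= windows$end[w]) next
      al <- expand_alleles(g[, s])
      n <- length(al)
      if (n < 2) next
      diffs <- 0; pairs <- 0
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        pairs <- pairs + 1
        if (al[i] != al[j]) diffs <- diffs + 1
      }
      tot <- tot + diffs / pairs
    }
    out[w] <- tot / (windows$end[w] - windows$start[w])
  }
  out
}

# windowed Watterson theta: segregating-site count with the window-median
# allele count in the harmonic number
brute_window_theta <- function(gm, samples, windows) {
  g <- gm$geno[samples, , drop = FALSE]
  out <- numeric(nrow(windows))
  for (w in seq_len(nrow(windows))) {
    ns <- integer(0)
    S <- 0
    for (s in seq_len(ncol(g))) {
      if (gm$sites$chrom[s] != windows$chrom[w]) next
      p0 <- gm$sites$pos[s] - 1L
      if (p0 < windows$start[w] || p0 >= windows$end[w]) next
      al <- expand_alleles(g[, s])
      if (length(al) >= 2 && sum(al) > 0 && sum(al) < length(al)) {
        S <- S + 1
        ns <- c(ns, length(al))
      }
    }
    if (S > 0) {
      a <- sum(1 / seq_len(round(stats::median(ns)) - 1))
      out[w] <- S / (a * (windows$end[w] - windows$start[w]))
    }
  }
  out
}

# Weir & Cockerham (1984) two-population a, b, c, transcribed literally
brute_wc_site <- function(codesA, codesB) {
  okA <- codesA >= 0; okB <- codesB >= 0
  n1 <- sum(okA); n2 <- sum(okB)
  if (n1 < 1 || n2 < 1 || (n1 + n2) < 3) return(NULL)
  p1 <- sum(codesA[okA]) / (2 * n1)
  p2 <- sum(codesB[okB]) / (2 * n2)
  if ((p1 == 0 && p2 == 0) || (p1 == 1 && p2 == 1)) return(NULL)
  h1 <- sum(codesA[okA] == 1) / n1
  h2 <- sum(codesB[okB] == 1) / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c <- hbar / 2
  c(a = a, b = b, c = c)
}

brute_window_fst <- function(gm, popA, popB, windows) {
  gA <- gm$geno[popA, , drop = FALSE]
  gB <- gm$geno[popB, , drop = FALSE]
  out <- rep(NA_real_, nrow(windows))
  for (w in seq_len(nrow(windows))) {
    sa <- 0; sabc <- 0; used <- 0
    for (s in seq_len(ncol(gA))) {
      if (gm$sites$chrom[s] != windows$chrom[w]) next
      p0 <- gm$sites$pos[s] - 1L
      if (p0 < windows$start[w] || p0 >= windows$end[w]) next
      comp <- brute_wc_site(gA[, s], gB[, s])
      if (is.null(comp)) next
      used <- used + 1
      sa <- sa + comp["a"]
      sabc <- sabc + sum(comp)
    }
    if (used > 0 && sabc != 0) out[w] <- sa / sabc
  }
  out
}

# exhaustive enumeration oracle for the sweep site model (n <= 8): loops over
# escape masks as bit patterns and computes the ancestral-configuration
# probabilities by explicit subset counting.
oracle_sweep_prob <- function(n, pe, bg) {
  stopifnot(n <= 8, length(bg) == n - 1)
  masks <- 0:(2^n - 1)
  popcnt <- vapply(masks, function(m) sum(bitwAnd(m, 2^(0:(n - 1))) > 0),
                   numeric(1))
  # hypergeometric by subset counting: H[[m]][k, k'+1] = P(|M ∩ D| = k' |
  # |M| = m, |D| = k) over uniform subsets of an n-set
  Hm <- lapply(1:n, function(m) {
    Ms <- masks[popcnt == m]
    H <- matrix(0, n - 1, m + 1)
    for (k in 1:(n - 1)) {
      Ds <- masks[popcnt == k]
      for (M in Ms) for (D in Ds) {
        kp <- sum(bitwAnd(bitwAnd(M, D), 2^(0:(n - 1))) > 0)
        H[k, kp + 1] <- H[k, kp + 1] + 1
      }
      H[k, ] <- H[k, ] / (length(Ms) * length(Ds))
    }
    H
  })
  raw <- numeric(n - 1)
  for (E in masks) {
    b <- popcnt[E + 1]
    wE <- pe^b * (1 - pe)^(n - b)
    if (wE == 0) next
    if (b == n) {
      raw <- raw + wE * bg
    } else {
      m <- b + 1
      H <- Hm[[m]]
      for (k in 1:(n - 1)) {
        for (kp in 0:m) {
          pr <- bg[k] * H[k, kp + 1]
          if (pr == 0) next
          pt <- kp / m
          if (pt > 0) {
            ko <- kp - 1 + (n - b)
            if (ko >= 1 && ko <= n - 1) raw[ko] <- raw[ko] + wE * pr * pt
          }
          if (pt < 1 && kp >= 1 && kp <= n - 1)
            raw[kp] <- raw[kp] + wE * pr * (1 - pt)
        }
      }
    }
  }
  tot <- sum(raw)
  if (tot == 0) rep(0, n - 1) else raw / tot
}

# quadratic brute-force interval intersector
brute_genes_in_regions <- function(regions, genes) {
  hit <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(regions))) {
      if (genes$chrom[i] == regions$chrom[j] &&
          genes$start[i] < regions$end[j] &&
          regions$start[j] < genes$end[i]) hit[i] <- TRUE
    }
  }
  sort(genes$gene[hit])
}
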