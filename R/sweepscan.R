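# SweepFinder/SweeD-style composite likelihood ratio scan.
#
# Model: at a grid position, each of the n sampled lineages at a nearby site
# escapes the sweep with probability p_e = 1 - exp(-lam * d) (d = bp distance,
# lam = per-bp escape intensity; large lam = weak/narrow sweep). The trapped
# lineages coalesce into a single ancestral lineage; the ancestral lineages
# draw a derived-allele configuration from the genome-wide background SFS
# (hypergeometric projection to their number), and the observed derived count
# is the escaped derived copies plus, if the trapped ancestor is derived, all
# trapped lineages. Likelihoods condition on polymorphism, as in SweepFinder.

#' Empirical site frequency spectrum
#'
#' Tallies per-site derived (unfolded) or minor (folded) allele counts over
#' polymorphic sites. Sites with missing calls are projected down to the modal
#' complete allele count by fractional hypergeometric projection before
#' tallying; sites with fewer alleles than the modal count are dropped.
#'
#' @param gm A [geno_matrix()].
#' @param samples Sample ids.
#' @param folded Fold to minor-allele counts (default TRUE; use FALSE when
#'   ancestral alleles are known, e.g. simulated data).
#' @return An `sfs` object: list with `n` (allele sample size), `probs`
#'   (over counts `1..n-1` unfolded or `1..floor(n/2)` folded), `folded`.
#' @export
empirical_sfs <- function(gm, samples, folded = TRUE) {
  ac <- site_allele_counts(gm, samples)
  poly <- ac$j > 0L & ac$j < ac$n & ac$n >= 2L
  if (!any(poly)) stop("no polymorphic site in the selected samples")
  j <- ac$j[poly]; n <- ac$n[poly]
  n0 <- as.integer(names(which.max(table(n))))
  tal <- numeric(n0 + 1)  # bins 0..n0
  at_n0 <- n == n0
  if (any(at_n0)) {
    t0 <- tabulate(j[at_n0] + 1L, nbins = n0 + 1L)
    tal <- tal + t0
  }
  above <- n > n0
  for (i in which(above)) {
    kk <- 0:n0
    tal <- tal + stats::dhyper(kk, j[i], n[i] - j[i], n0)
  }
  probs <- tal[2:n0]  # counts 1..n0-1
  if (sum(probs) == 0) stop("no polymorphic mass after projection")
  probs <- probs / sum(probs)
  if (folded) {
    half <- floor(n0 / 2)
    fp <- vapply(seq_len(half), function(k)
      if (k < n0 - k) probs[k] + probs[n0 - k] else probs[k], numeric(1))
    structure(list(n = n0, probs = fp, folded = TRUE), class = "sfs")
  } else {
    structure(list(n = n0, probs = probs, folded = FALSE), class = "sfs")
  }
}

#' Project an SFS to a smaller sample size
#'
#' Standard hypergeometric projection
#' `P(k'|m) = sum_k P(k|n) * Hyper(k'; n, k, m)`, renormalized over the
#' polymorphic classes `1..m-1`.
#'
#' @param sfs An unfolded `sfs` object.
#' @param m Target allele count, `2 <= m <= n`.
#' @return An `sfs` object at size `m`.
#' @export
project_sfs <- function(sfs, m) {
  if (sfs$folded) stop("project unfolded spectra (fold afterwards)")
  n <- sfs$n
  if (m > n) stop("cannot project upward (m > n)")
  if (m < 2) stop("m must be >= 2")
  if (m == n) return(sfs)
  k <- seq_len(n - 1)
  probs_m <- vapply(seq_len(m - 1), function(kp)
    sum(sfs$probs * stats::dhyper(kp, k, n - k, m)), numeric(1))
  probs_m <- probs_m / sum(probs_m)
  structure(list(n = as.integer(m), probs = probs_m, folded = FALSE),
            class = "sfs")
}

# symmetric unfolded representation of a (possibly folded) background SFS
unfold_sym <- function(sfs) {
  if (!sfs$folded) return(sfs)
  n <- sfs$n
  u <- numeric(n - 1)
  for (k in seq_along(sfs$probs)) {
    if (k < n - k) {
      u[k] <- u[k] + sfs$probs[k] / 2
      u[n - k] <- u[n - k] + sfs$probs[k] / 2
    } else u[k] <- sfs$probs[k]
  }
  structure(list(n = n, probs = u, folded = FALSE), class = "sfs")
}

# p_e-independent kernel: G[B+1, k_obs] = P(observe polymorphic k_obs | B
# escaped lineages), for B = 0..n, k_obs = 1..n-1, under background bg
# (unfolded probs over 1..n-1 at size n).
sweep_kernel <- function(n, bg) {
  G <- matrix(0, n + 1, n - 1)
  k <- seq_len(n - 1)
  G[n + 1, ] <- bg  # B = n: all escape, background applies directly
  for (B in 0:(n - 1)) {
    m <- B + 1L
    # projection of the background to the m ancestral lineages, incl. 0 and m
    proj <- vapply(0:m, function(kp)
      sum(bg * stats::dhyper(kp, k, n - k, m)), numeric(1))
    for (kp in 0:m) {
      if (proj[kp + 1] == 0) next
      pt <- kp / m  # trapped ancestor is derived (exchangeability)
      if (pt > 0) {
        ko <- kp - 1L + (n - B)  # trapped lineages all derived
        if (ko >= 1 && ko <= n - 1)
          G[B + 1, ko] <- G[B + 1, ko] + proj[kp + 1] * pt
      }
      if (pt < 1 && kp >= 1 && kp <= n - 1)
        G[B + 1, kp] <- G[B + 1, kp] + proj[kp + 1] * (1 - pt)
    }
  }
  G
}

# renormalized sweep-model probabilities for a vector of escape probabilities:
# rows = p_e values, cols = derived counts 1..n-1
sweep_model_probs <- function(n, pe, bg) {
  G <- sweep_kernel(n, bg)
  W <- vapply(0:n, function(B) stats::dbinom(B, n, pe), numeric(length(pe)))
  if (length(pe) == 1L) W <- matrix(W, nrow = 1)
  P <- W %*% G
  tot <- rowSums(P)
  P[tot > 0, ] <- P[tot > 0, , drop = FALSE] / tot[tot > 0]
  P[tot == 0, ] <- 0
  P
}

#' Sweep-model probability of an observed allele count
#'
#' Probability of observing a polymorphic derived-allele count `k` (minor
#' count when `sfs$folded`) among `n` alleles at a site `d` bp from the sweep
#' position, under escape intensity `lam`, conditioned on polymorphism. In the
#' full-escape limit (`lam * d >> 1`) this reduces to the background SFS
#' probability; with no escape possible (`p_e = 0`) any polymorphic outcome
#' has probability 0.
#'
#' @param k Observed allele count (1..n-1; minor count if folded).
#' @param n Allele sample size at the site.
#' @param d Distance to the evaluated grid position, bp.
#' @param lam Sweep escape intensity per bp (>= 0; `Inf` = background).
#' @param sfs Background SFS ([empirical_sfs()]); projected to `n` if larger.
#' @return Probability (numeric scalar or vector along `k`).
#' @export
sweep_site_prob <- function(k, n, d, lam, sfs) {
  if (any(lam < 0)) stop("lam must be >= 0")
  stopifnot(length(d) == 1, length(lam) == 1, length(n) == 1)
  folded <- sfs$folded
  bg <- unfold_sym(sfs)
  if (bg$n != n) bg <- project_sfs(bg, n)
  pe <- if (is.infinite(lam)) 1 else 1 - exp(-lam * d)
  P <- sweep_model_probs(n, pe, bg$probs)[1, ]
  if (folded) {
    vapply(k, function(kk) {
      if (kk < 1 || kk > floor(n / 2)) return(0)
      if (kk < n - kk) P[kk] + P[n - kk] else P[kk]
    }, numeric(1))
  } else {
    ifelse(k >= 1 & k <= n - 1, P[pmax(pmin(k, n - 1), 1)], 0)
  }
}

#' Composite likelihood ratio scan for selective sweeps
#'
#' Evaluates, at `grid_per_chrom` equally spaced positions per chromosome, the
#' composite likelihood of the observed polymorphic sites under the sweep
#' model maximized over a grid of escape intensities, against the genome-wide
#' background SFS: `CLR = 2 * max_lam sum_sites [ln P_sweep - ln P_bg]`,
#' floored at 0 (the background itself, p_e = 1, is always an admissible
#' model, so CLR >= 0 everywhere). Sites farther than the distance where
#' `p_e > pe_max` contribute identically to both models and are skipped. For
#' speed, sites are binned into `n_shells` log-spaced shells of `lam * d`
#' with exact model probabilities at each shell's representative value.
#'
#' Sites whose allele sample size differs from the modal complete count are
#' excluded from the scan.
#'
#' @param gm A [geno_matrix()].
#' @param samples Sample ids of the scanned group.
#' @param grid_per_chrom Evaluation positions per chromosome (default 2000).
#' @param lam_grid Escape intensities per bp; default 20 log-spaced values
#'   from 1e-6 (p_e at 1 bp ~ 1e-6) to -ln(0.01)/1e4 (p_e at 10 kb = 0.99).
#' @param folded Use the folded spectrum (default TRUE; FALSE when ancestral
#'   alleles are known).
#' @param contig_lengths Named vector of contig lengths; defaults to the
#'   maximum site position per contig.
#' @param n_shells Number of distance shells (default 48).
#' @param pe_max Escape probability beyond which sites are skipped
#'   (default 0.9999).
#' @return data.frame with `chrom`, `pos` (grid position), `clr`,
#'   `lambda_hat` (maximizing intensity; `NA` where the background wins).
#' @export
clr_scan <- function(gm, samples, grid_per_chrom = 2000, lam_grid = NULL,
                     folded = TRUE, contig_lengths = NULL, n_shells = 48,
                     pe_max = 0.9999) {
  if (is.null(lam_grid))
    lam_grid <- exp(seq(log(1e-6), log(-log(1 - 0.99) / 1e4), length.out = 20))
  if (!length(lam_grid)) stop("empty lam_grid")
  lam_grid <- lam_grid[is.finite(lam_grid)]  # sentinel is implicit (CLR >= 0)
  sfs <- empirical_sfs(gm, samples, folded = folded)
  n0 <- sfs$n
  bg <- unfold_sym(sfs)
  ac <- site_allele_counts(gm, samples)
  poly <- ac$j > 0L & ac$j < ac$n & ac$n >= 2L
  at_n0 <- poly & ac$n == n0
  if (sum(at_n0) < sum(poly))
    message(sum(poly) - sum(at_n0),
            " polymorphic site(s) not at the modal allele count excluded")
  kval <- if (folded) pmin(ac$j, n0 - ac$j) else ac$j
  classes <- if (folded) seq_len(floor(n0 / 2)) else seq_len(n0 - 1)
  # fold helper on unfolded probability matrix (rows = p_e, cols = 1..n0-1)
  fold_probs <- function(P) {
    if (!folded) return(P)
    vapply(classes, function(kk)
      if (kk < n0 - kk) P[, kk] + P[, n0 - kk] else P[, kk],
      numeric(nrow(P)))
  }
  bg_class <- as.numeric(fold_probs(matrix(bg$probs, nrow = 1)))
  # distance shells in s = lam * d
  s_max <- -log(1 - pe_max)
  s_breaks <- c(0, exp(seq(log(1e-7), log(s_max), length.out = n_shells)))
  s_rep <- sqrt(pmax(s_breaks[-length(s_breaks)], s_breaks[2] / 4) *
                  s_breaks[-1])
  pe_rep <- 1 - exp(-s_rep)
  Psw <- fold_probs(sweep_model_probs(n0, pe_rep, bg$probs))
  if (is.null(dim(Psw))) Psw <- matrix(Psw, nrow = length(pe_rep))
  LR <- log(pmax(Psw, 1e-300)) - matrix(log(bg_class), nrow = n_shells,
                                        ncol = length(classes), byrow = TRUE)
  # telescoped boundary coefficients: contribution_k(g) =
  # sum_b coef[b, k] * (F_k(g + d_b) - F_k(g - d_b)), d_b = s_breaks[b] / lam
  coef <- rbind(LR, 0) - rbind(0, LR)  # (n_shells + 1) x classes
  coef <- -coef  # c_b = LR_{b-1} - LR_b, with LR_0 = LR_{J+1} = 0
  if (is.null(contig_lengths)) {
    contig_lengths <- tapply(gm$sites$pos, gm$sites$chrom, max)
    contig_lengths <- stats::setNames(as.numeric(contig_lengths),
                                      names(contig_lengths))
  }
  out <- list()
  for (ch in names(contig_lengths)) {
    L <- contig_lengths[[ch]]
    grid <- (seq_len(grid_per_chrom) - 0.5) * L / grid_per_chrom
    sel <- at_n0 & gm$sites$chrom == ch
    pos_by_k <- split(gm$sites$pos[sel], kval[sel])
    best <- rep(0, grid_per_chrom)
    best_lam <- rep(NA_real_, grid_per_chrom)
    for (lam in lam_grid) {
      d_b <- s_breaks / lam
      tot <- numeric(grid_per_chrom)
      for (kk in names(pos_by_k)) {
        ki <- match(as.integer(kk), classes)
        if (is.na(ki)) next
        pk <- pos_by_k[[kk]]
        for (b in seq_along(d_b)) {
          cb <- coef[b, ki]
          if (cb == 0) next
          tot <- tot + cb * (findInterval(grid + d_b[b], pk) -
                               findInterval(grid - d_b[b], pk))
        }
      }
      better <- tot > best
      best[better] <- tot[better]
      best_lam[better] <- lam
    }
    out[[ch]] <- data.frame(chrom = ch, pos = grid, clr = 2 * best,
                            lambda_hat = best_lam)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
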