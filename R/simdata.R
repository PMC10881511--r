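# Mosaic crop/wild/weed cohort simulator with machine-readable truth.
#
# The generator is a copying/mosaic model, not a coalescent: wild haplotypes
# carry neutral-SFS mutations placed as a Poisson process; the crop is founded
# from a small number of wild haplotypes (domestication bottleneck) plus
# crop-lineage private mutations, then selfed; weeds are de-domesticated crop
# copies, crop x wild tract mosaics, or F1 hybrids. Ancestry tract truth is
# exact by construction. All randomness uses R's default Mersenne-Twister
# stream, seeded once per cohort.

#' Scenario configuration for the cohort simulator
#'
#' Defaults emulate a scaled-down resequencing cohort: a diverse selfing wild
#' panel, a bottlenecked crop derived from it, and three weed strains
#' (de-domesticated, wild-introgressed, recent F1 hybrids), with localized
#' selective sweeps injected into weed strains.
#'
#' @param n_wild,n_crop Number of wild / crop individuals.
#' @param n_weed Named integer vector of weed strain sizes; names from
#'   `dedomesticated`, `introgressed`, `f1`.
#' @param n_outgroup Number of outgroup individuals (divergent, homozygous).
#' @param contig_lengths Named vector of contig lengths (bp).
#' @param theta_wild Expected per-bp nucleotide diversity of the wild panel.
#' @param theta_crop_mut Per-bp theta for crop-lineage private mutations
#'   (post-bottleneck variants absent from wild).
#' @param theta_outgroup Per-bp density of fixed outgroup-private differences.
#' @param crop_bottleneck_k Number of wild founder haplotypes for the crop.
#' @param bottleneck_fixation Probability that a founder-polymorphic site is
#'   driven to fixation (one founder's allele, frequency-weighted) by drift
#'   and selection during the domestication bottleneck; controls the crop's
#'   diversity loss relative to wild.
#' @param selfing_generations Selfing generations applied to crop and selfed
#'   weeds; heterozygosity halves each generation in expectation.
#' @param wild_selfing Selfing generations applied to the emitted wild
#'   samples (the haplotype pool itself is untouched); models the mixed
#'   mating system of wild rice, whose accessions are largely homozygous.
#' @param introgression_fraction Expected fraction of an introgressed weed's
#'   genome covered by wild tracts.
#' @param tract_length_mean Mean wild tract length (bp, exponential; >= 10 kb).
#' @param sweep_intervals data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `group` naming the target sample group, or NULL.
#' @param crossover_rate Crossovers per bp per gamete (default 1 per 10 Mb).
#' @param sweep_flank Width (bp) of the flank over which diversity recovers
#'   around a sweep core.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_wild = 16,
                            n_crop = 16,
                            n_weed = c(dedomesticated = 10, introgressed = 10, f1 = 4),
                            n_outgroup = 1,
                            contig_lengths = c(chr1 = 4e6, chr2 = 2e6),
                            theta_wild = 0.005,
                            theta_crop_mut = 0.001,
                            theta_outgroup = 0.001,
                            crop_bottleneck_k = 8,
                            bottleneck_fixation = 0.4,
                            selfing_generations = 10,
                            wild_selfing = 2,
                            introgression_fraction = 0.2,
                            tract_length_mean = 1e6,
                            sweep_intervals = data.frame(
                              chrom = c("chr1", "chr2"),
                              start = c(2.5e6, 0.6e6),
                              end = c(2.7e6, 0.8e6),
                              group = c("weed_dd", "weed_ix")),
                            crossover_rate = 1e-7,
                            sweep_flank = 5e4,
                            seed = 1L) {
  cfg <- list(n_wild = n_wild, n_crop = n_crop, n_weed = n_weed,
              n_outgroup = n_outgroup, contig_lengths = contig_lengths,
              theta_wild = theta_wild, theta_crop_mut = theta_crop_mut,
              theta_outgroup = theta_outgroup,
              crop_bottleneck_k = crop_bottleneck_k,
              bottleneck_fixation = bottleneck_fixation,
              selfing_generations = selfing_generations,
              wild_selfing = wild_selfing,
              introgression_fraction = introgression_fraction,
              tract_length_mean = tract_length_mean,
              sweep_intervals = sweep_intervals,
              crossover_rate = crossover_rate,
              sweep_flank = sweep_flank, seed = seed)
  validate_scenario(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario <- function(cfg) {
  stopifnot(cfg$n_wild >= 1, cfg$n_crop >= 1, all(cfg$n_weed >= 1),
            cfg$n_outgroup >= 0,
            !is.null(names(cfg$contig_lengths)), all(cfg$contig_lengths > 0),
            cfg$theta_wild >= 0, cfg$theta_crop_mut >= 0,
            cfg$crop_bottleneck_k >= 1,
            cfg$bottleneck_fixation >= 0, cfg$bottleneck_fixation <= 1,
            cfg$selfing_generations >= 0, cfg$wild_selfing >= 0,
            cfg$crossover_rate >= 0)
  if (!all(names(cfg$n_weed) %in% c("dedomesticated", "introgressed", "f1")))
    stop("weed modes must be from dedomesticated / introgressed / f1")
  if (cfg$introgression_fraction <= 0 && "introgressed" %in% names(cfg$n_weed) ||
      cfg$introgression_fraction >= 1)
    if (cfg$introgression_fraction < 0 || cfg$introgression_fraction >= 1)
      stop("introgression_fraction must be in [0, 1)")
  if (cfg$tract_length_mean < 1e4) stop("tract_length_mean must be >= 10 kb")
  if (cfg$crop_bottleneck_k > 2 * cfg$n_wild)
    stop("crop_bottleneck_k exceeds wild haplotype count")
  if (!is.null(cfg$sweep_intervals) && nrow(cfg$sweep_intervals)) {
    sw <- cfg$sweep_intervals
    stopifnot(all(c("chrom", "start", "end", "group") %in% names(sw)))
    for (g in unique(sw$group)) {
      for (ch in unique(sw$chrom)) {
        s <- sw[sw$group == g & sw$chrom == ch, ]
        if (nrow(s) > 1) {
          s <- s[order(s$start), ]
          if (any(s$start[-1] < s$end[-nrow(s)]))
            stop("overlapping sweep intervals for group ", g)
        }
      }
    }
  }
  invisible(cfg)
}

# ---- low-level building blocks ------------------------------------------

# derived-allele counts from the neutral SFS: P(i) proportional to 1/i
rneutral_counts <- function(S, n_alleles) {
  if (S == 0L || n_alleles < 2L) return(integer(0))
  i <- seq_len(n_alleles - 1L)
  sample(i, S, replace = TRUE, prob = 1 / i)
}

# 0/1 haplotype matrix with given per-site derived-allele counts
place_mutations <- function(n_hap, counts) {
  S <- length(counts)
  H <- matrix(0L, n_hap, S)
  if (S) {
    carriers <- lapply(counts, function(i) sample.int(n_hap, i))
    H[cbind(unlist(carriers), rep.int(seq_len(S), counts))] <- 1L
  }
  H
}

# one gamete as a recombinant mosaic of the rows of HF
founder_gamete <- function(HF, pos, L, rate) {
  k <- nrow(HF)
  if (k == 1L) return(HF[1L, ])
  nx <- stats::rpois(1, L * rate)
  breaks <- sort(stats::runif(nx, 0, L))
  seg <- findInterval(pos, breaks) + 1L
  fid <- sample.int(k, nx + 1L, replace = TRUE)
  HF[cbind(fid[seg], seq_along(pos))]
}

# meiotic gamete from a diploid pair of haplotypes
recombine_gamete <- function(h1, h2, pos, L, rate) {
  nx <- stats::rpois(1, L * rate)
  start <- sample.int(2L, 1L) - 1L
  if (nx == 0L) return(if (start == 0L) h1 else h2)
  breaks <- sort(stats::runif(nx, 0, L))
  phase <- (findInterval(pos, breaks) + start) %% 2L
  g <- h1
  sw <- phase == 1L
  g[sw] <- h2[sw]
  g
}

# self an individual (rows 2i-1, 2i of H) for `gens` generations
self_pair <- function(h1, h2, pos, L, rate, gens) {
  for (g in seq_len(gens)) {
    n1 <- recombine_gamete(h1, h2, pos, L, rate)
    n2 <- recombine_gamete(h1, h2, pos, L, rate)
    h1 <- n1; h2 <- n2
  }
  list(h1, h2)
}

merge_intervals <- function(start, end) {
  if (!length(start)) return(data.frame(start = numeric(0), end = numeric(0)))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- c(); out_e <- c()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- start[i]; me <- end[i] }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

# ---- panel-level operations ---------------------------------------------

new_hap_panel <- function(contigs, contig_lengths) {
  structure(list(contigs = contigs, contig_lengths = contig_lengths),
            class = "hap_panel")
}

#' Simulate the wild haplotype pool
#'
#' Places segregating sites as a Poisson process with expectation
#' `theta_wild * a_{2n-1} * L` per contig and draws derived-allele counts from
#' the neutral frequency spectrum (P(i) proportional to 1/i). The reference
#' allele is ancestral throughout. Deterministic given `cfg$seed`.
#'
#' @param cfg A [scenario_config()].
#' @return A `hap_panel`: per contig, sorted positions and a
#'   `2*n_wild x S` 0/1 haplotype matrix.
#' @export
simulate_wild_panel <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_hap <- 2L * cfg$n_wild
  a <- if (n_hap >= 2) sum(1 / seq_len(n_hap - 1L)) else 0
  contigs <- lapply(cfg$contig_lengths, function(L) {
    S <- stats::rpois(1, cfg$theta_wild * a * L)
    S <- min(S, L)
    pos <- sort(sample.int(L, S))
    H <- place_mutations(n_hap, rneutral_counts(S, n_hap))
    list(pos = pos, H = H)
  })
  names(contigs) <- names(cfg$contig_lengths)
  new_hap_panel(contigs, cfg$contig_lengths)
}

#' Simulate the bottlenecked, selfing crop
#'
#' Crop haplotypes are recombinant mosaics of `crop_bottleneck_k` founder
#' haplotypes drawn from the wild pool, carrying additional crop-lineage
#' private mutations, followed by `selfing_generations` generations of selfing
#' (expected heterozygosity halves each generation).
#'
#' @param wild_pool Output of [simulate_wild_panel()].
#' @param cfg A [scenario_config()].
#' @return A `hap_panel` of `2*n_crop` haplotypes whose site set is the union
#'   of wild sites and crop-private mutation sites, with attribute `founders`
#'   (the founder `hap_panel`).
#' @export
simulate_crop <- function(wild_pool, cfg) {
  k <- cfg$crop_bottleneck_k
  n_pool <- nrow(wild_pool$contigs[[1]]$H)
  if (k > n_pool) stop("crop_bottleneck_k exceeds wild haplotype count")
  founder_rows <- sample.int(n_pool, k)
  a_k <- if (k >= 2) sum(1 / seq_len(k - 1L)) else 0
  founders <- list()
  contigs <- list()
  for (ch in names(wild_pool$contigs)) {
    wc <- wild_pool$contigs[[ch]]
    L <- wild_pool$contig_lengths[[ch]]
    # founder copies of the wild haplotypes, with a fraction of sites driven
    # to fixation by drift/selection during the domestication bottleneck
    HFw <- wc$H[founder_rows, , drop = FALSE]
    if (cfg$bottleneck_fixation > 0 && ncol(HFw) > 0 && k > 1) {
      fix <- which(stats::runif(ncol(HFw)) < cfg$bottleneck_fixation)
      if (length(fix)) {
        pick <- sample.int(k, length(fix), replace = TRUE)
        HFw[, fix] <- matrix(HFw[cbind(pick, fix)], nrow = k, ncol = length(fix),
                             byrow = TRUE)
      }
    }
    # crop-lineage private mutations on the founder haplotypes
    Sc <- if (k >= 2) stats::rpois(1, cfg$theta_crop_mut * a_k * L) else 0L
    pos_c <- integer(0)
    if (Sc > 0) {
      pos_c <- setdiff(sample.int(L, min(Sc + length(wc$pos), L)), wc$pos)[seq_len(Sc)]
      pos_c <- sort(pos_c[!is.na(pos_c)])
    }
    HC <- place_mutations(k, rneutral_counts(length(pos_c), k))
    pos_all <- sort(c(wc$pos, pos_c))
    iw <- match(wc$pos, pos_all)
    ic <- match(pos_c, pos_all)
    HF <- matrix(0L, k, length(pos_all))
    if (length(iw)) HF[, iw] <- HFw
    if (length(ic)) HF[, ic] <- HC
    H <- matrix(0L, 2L * cfg$n_crop, length(pos_all))
    for (i in seq_len(cfg$n_crop)) {
      h1 <- founder_gamete(HF, pos_all, L, cfg$crossover_rate)
      h2 <- founder_gamete(HF, pos_all, L, cfg$crossover_rate)
      hh <- self_pair(h1, h2, pos_all, L, cfg$crossover_rate,
                      cfg$selfing_generations)
      H[2L * i - 1L, ] <- hh[[1]]
      H[2L * i, ] <- hh[[2]]
    }
    contigs[[ch]] <- list(pos = pos_all, H = H)
    founders[[ch]] <- list(pos = pos_all, H = HF)
  }
  out <- new_hap_panel(contigs, wild_pool$contig_lengths)
  attr(out, "founders") <- new_hap_panel(founders, wild_pool$contig_lengths)
  attr(out, "founder_rows") <- founder_rows
  out
}

#' Simulate one weed strain
#'
#' Three origins are modeled: `dedomesticated` weeds are outcrossed draws from
#' the crop followed by selfing; `introgressed` weeds are a crop background
#' carrying exponentially distributed wild tracts (pasted onto both
#' haplotypes, then selfed), the tracts covering `introgression_fraction` of
#' the genome in expectation; `f1` weeds are one crop gamete plus one wild
#' gamete with no selfing.
#'
#' @param crop Output of [simulate_crop()].
#' @param wild_pool Output of [simulate_wild_panel()].
#' @param mode One of `"dedomesticated"`, `"introgressed"`, `"f1"`.
#' @param cfg A [scenario_config()].
#' @param n Number of weed individuals (defaults to `cfg$n_weed[mode]`).
#' @return List with `panel` (a `hap_panel` on the crop site set) and
#'   `tracts` (per-sample ancestry truth, 0-based half-open; `NULL` for F1
#'   hybrids, whose ancestry is heterozygous genome-wide).
#' @export
simulate_weed <- function(crop, wild_pool, mode, cfg, n = NULL) {
  mode <- match.arg(mode, c("dedomesticated", "introgressed", "f1"))
  if (is.null(n)) n <- unname(cfg$n_weed[[mode]])
  n_crop <- nrow(crop$contigs[[1]]$H) / 2L
  n_pool <- nrow(wild_pool$contigs[[1]]$H)
  contigs <- lapply(crop$contigs, function(cc)
    list(pos = cc$pos, H = matrix(0L, 2L * n, length(cc$pos))))
  tracts <- list()
  for (i in seq_len(n)) {
    for (ch in names(crop$contigs)) {
      cc <- crop$contigs[[ch]]
      wc <- wild_pool$contigs[[ch]]
      L <- crop$contig_lengths[[ch]]
      iw <- match(wc$pos, cc$pos)  # wild sites within the crop site set
      if (mode == "dedomesticated") {
        p1 <- sample.int(n_crop, 1L); p2 <- sample.int(n_crop, 1L)
        h1 <- recombine_gamete(cc$H[2L * p1 - 1L, ], cc$H[2L * p1, ], cc$pos, L,
                               cfg$crossover_rate)
        h2 <- recombine_gamete(cc$H[2L * p2 - 1L, ], cc$H[2L * p2, ], cc$pos, L,
                               cfg$crossover_rate)
        hh <- self_pair(h1, h2, cc$pos, L, cfg$crossover_rate,
                        cfg$selfing_generations)
        tr <- data.frame(chrom = ch, start = 0, end = L, origin = "crop")
      } else if (mode == "f1") {
        p <- sample.int(n_crop, 1L)
        h1 <- recombine_gamete(cc$H[2L * p - 1L, ], cc$H[2L * p, ], cc$pos, L,
                               cfg$crossover_rate)
        w <- sample.int(n_pool / 2L, 1L)
        wg <- recombine_gamete(wc$H[2L * w - 1L, ], wc$H[2L * w, ], wc$pos, L,
                               cfg$crossover_rate)
        h2 <- integer(length(cc$pos))
        h2[iw] <- wg
        hh <- list(h1, h2)
        tr <- NULL
      } else { # introgressed
        p <- sample.int(n_crop, 1L)
        h1 <- cc$H[2L * p - 1L, ]
        h2 <- cc$H[2L * p, ]
        n_tr <- stats::rpois(1, cfg$introgression_fraction * L / cfg$tract_length_mean)
        ts <- te <- numeric(0)
        if (n_tr > 0) {
          len <- stats::rexp(n_tr, 1 / cfg$tract_length_mean)
          st <- stats::runif(n_tr, -len, L)
          ts <- pmax(0, st); te <- pmin(L, st + len)
          keep <- te > ts
          m <- merge_intervals(ts[keep], te[keep])
          ts <- m$start; te <- m$end
        }
        for (t in seq_along(ts)) {
          in_tr <- cc$pos > ts[t] & cc$pos <= te[t]
          wA <- wc$H[sample.int(n_pool, 1L), ]
          wB <- wc$H[sample.int(n_pool, 1L), ]
          extA <- integer(length(cc$pos)); extA[iw] <- wA
          extB <- integer(length(cc$pos)); extB[iw] <- wB
          h1[in_tr] <- extA[in_tr]
          h2[in_tr] <- extB[in_tr]
        }
        hh <- self_pair(h1, h2, cc$pos, L, cfg$crossover_rate,
                        cfg$selfing_generations)
        tr <- if (length(ts)) {
          cs <- c(0, te); ce <- c(ts, L)
          crop_iv <- data.frame(start = cs, end = ce)[cs < ce, , drop = FALSE]
          rbind(data.frame(chrom = ch, start = ts, end = te, origin = "wild"),
                data.frame(chrom = rep(ch, nrow(crop_iv)),
                           start = crop_iv$start,
                           end = crop_iv$end,
                           origin = rep("crop", nrow(crop_iv))))
        } else data.frame(chrom = ch, start = 0, end = L, origin = "crop")
      }
      contigs[[ch]]$H[2L * i - 1L, ] <- hh[[1]]
      contigs[[ch]]$H[2L * i, ] <- hh[[2]]
      if (!is.null(tr)) {
        tr$sample_idx <- i
        tracts[[length(tracts) + 1L]] <- tr
      }
    }
  }
  list(panel = new_hap_panel(contigs, crop$contig_lengths),
       tracts = if (length(tracts)) do.call(rbind, tracts) else NULL)
}

#' Inject a selective sweep into a group's haplotypes
#'
#' Inside the core interval all haplotypes of the panel are replaced by one
#' randomly chosen haplotype (a complete wipe-out of local diversity), a
#' Poisson(`theta * core_length / 10`) sprinkle of new singleton mutations is
#' re-added, and diversity recovers over a flank on each side: each haplotype
#' copies the sweep haplotype from the core edge up to an independent
#' Uniform(0, flank) breakpoint, emulating recombinational escape during the
#' sweep.
#'
#' @param panel A `hap_panel` (the target group's haplotypes).
#' @param chrom Contig name.
#' @param start,end Core interval, 0-based half-open, within the contig.
#' @param theta Per-bp theta controlling the singleton sprinkle.
#' @param flank Flank width in bp (default 50 kb).
#' @return The modified `hap_panel`; attribute `sweep_truth` accumulates the
#'   injected intervals.
#' @export
inject_sweep <- function(panel, chrom, start, end, theta, flank = 5e4) {
  cc <- panel$contigs[[chrom]]
  if (is.null(cc)) stop("unknown contig: ", chrom)
  L <- panel$contig_lengths[[chrom]]
  if (start < 0 || end > L || end <= start) stop("sweep interval outside contig")
  n_hap <- nrow(cc$H)
  donor_row <- sample.int(n_hap, 1L)
  donor <- cc$H[donor_row, ]
  core <- cc$pos > start & cc$pos <= end
  for (r in seq_len(n_hap)) cc$H[r, core] <- donor[core]
  # flanks: per-haplotype recombinational escape breakpoints
  for (side in c("left", "right")) {
    d <- if (side == "left") start - cc$pos + 1 else cc$pos - end
    in_flank <- d > 0 & d <= flank
    if (!any(in_flank)) next
    df <- d[in_flank]
    for (r in seq_len(n_hap)) {
      u <- stats::runif(1, 0, flank)
      sel <- which(in_flank)[df < u]
      cc$H[r, sel] <- donor[sel]
    }
  }
  # singleton sprinkle restores a trace of diversity inside the core
  S_new <- stats::rpois(1, theta * (end - start) / 10)
  if (S_new > 0) {
    cand <- start + sample.int(end - start, min(S_new * 2L, end - start))
    cand <- setdiff(cand, cc$pos)[seq_len(min(S_new, length(setdiff(cand, cc$pos))))]
    cand <- sort(cand[!is.na(cand)])
    if (length(cand)) {
      Hn <- matrix(0L, n_hap, length(cand))
      Hn[cbind(sample.int(n_hap, length(cand), replace = TRUE),
               seq_along(cand))] <- 1L
      pos_all <- c(cc$pos, cand)
      o <- order(pos_all)
      cc$H <- cbind(cc$H, Hn)[, o, drop = FALSE]
      cc$pos <- pos_all[o]
    }
  }
  panel$contigs[[chrom]] <- cc
  attr(panel, "sweep_truth") <- rbind(
    attr(panel, "sweep_truth"),
    data.frame(chrom = chrom, start = start, end = end,
               donor_hap = donor_row))
  panel
}

# replace each sample's ancestry inside a sweep core with the donor sample's
# ancestry there (the sweep copies one haplotype across the whole group)
rewrite_tracts_for_sweep <- function(tr, chrom, cs, ce, donor_sample) {
  donor_core <- tr[tr$sample == donor_sample & tr$chrom == chrom &
                     tr$end > cs & tr$start < ce, , drop = FALSE]
  donor_core$start <- pmax(donor_core$start, cs)
  donor_core$end <- pmin(donor_core$end, ce)
  out <- list()
  for (s in unique(tr$sample)) {
    rows <- tr[tr$sample == s, , drop = FALSE]
    keep <- rows[rows$chrom != chrom, , drop = FALSE]
    ch_rows <- rows[rows$chrom == chrom, , drop = FALSE]
    clipped <- list()
    for (i in seq_len(nrow(ch_rows))) {
      r <- ch_rows[i, ]
      if (r$start < cs) {
        rr <- r; rr$end <- min(r$end, cs)
        if (rr$end > rr$start) clipped[[length(clipped) + 1]] <- rr
      }
      if (r$end > ce) {
        rr <- r; rr$start <- max(r$start, ce)
        if (rr$end > rr$start) clipped[[length(clipped) + 1]] <- rr
      }
    }
    core <- donor_core
    if (nrow(core)) core$sample <- s
    new_ch <- rbind(do.call(rbind, clipped), core)
    new_ch <- new_ch[order(new_ch$start), , drop = FALSE]
    # merge adjacent same-origin intervals
    if (nrow(new_ch) > 1) {
      keep_row <- rep(TRUE, nrow(new_ch))
      for (i in 2:nrow(new_ch)) {
        j <- max(which(keep_row[seq_len(i - 1)]))
        if (new_ch$origin[i] == new_ch$origin[j] &&
            new_ch$start[i] <= new_ch$end[j]) {
          new_ch$end[j] <- max(new_ch$end[j], new_ch$end[i])
          keep_row[i] <- FALSE
        }
      }
      new_ch <- new_ch[keep_row, , drop = FALSE]
    }
    out[[s]] <- rbind(keep, new_ch)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Collapse a haplotype panel to diploid genotypes
#'
#' Pairs consecutive haplotype rows (2i-1, 2i) into individuals and returns a
#' [geno_matrix()] over the panel's site set. Reference alleles are ancestral;
#' ref/alt bases are assigned deterministically from the position.
#'
#' @param panel A `hap_panel`.
#' @param sample_ids Sample names (length = rows/2).
#' @return A [geno_matrix()].
#' @export
haps_to_genotypes <- function(panel, sample_ids) {
  n <- nrow(panel$contigs[[1]]$H) / 2L
  stopifnot(length(sample_ids) == n)
  geno <- NULL
  sites <- NULL
  for (ch in names(panel$contigs)) {
    cc <- panel$contigs[[ch]]
    g <- cc$H[seq(1, 2 * n, by = 2), , drop = FALSE] +
      cc$H[seq(2, 2 * n, by = 2), , drop = FALSE]
    geno <- cbind(geno, g)
    sites <- rbind(sites, data.frame(chrom = ch, pos = cc$pos,
                                     stringsAsFactors = FALSE))
  }
  ra <- assign_alleles(sites$pos)
  sites$ref <- ra$ref; sites$alt <- ra$alt
  geno_matrix(geno, sample_ids, sites)
}

# deterministic ref/alt bases from position (keeps cohorts reproducible
# without consuming the RNG stream)
assign_alleles <- function(pos) {
  b <- c("A", "C", "G", "T")
  r <- (pos %% 4L) + 1L
  a <- ((pos %/% 4L) %% 3L) + 1L
  others <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  list(ref = b[r], alt = b[others[cbind(r, a)]])
}

#' Simulate a full cohort with truth
#'
#' Generates the wild panel, crop, weed strains and outgroup of `cfg`, applies
#' the configured sweeps to their target groups, and assembles a single
#' genotype matrix over the union of all segregating sites, together with the
#' population map and the truth set (ancestry tracts for selfed weeds, sweep
#' intervals, realized parameters).
#'
#' @param cfg A [scenario_config()].
#' @return A list of class `cohort`: `gm` ([geno_matrix()]), `popmap`
#'   (data.frame sample/group/role), `truth` (list with `tracts`, `sweeps`,
#'   `params`), and `cfg`.
#' @export
simulate_cohort <- function(cfg) {
  validate_scenario(cfg)
  wild <- simulate_wild_panel(cfg)   # seeds the stream from cfg$seed
  crop <- simulate_crop(wild, cfg)
  # emitted wild samples are partially inbred (mixed mating); the pool used
  # for founders and introgression donors keeps its original haplotypes
  wild_samples <- wild
  if (cfg$wild_selfing > 0) {
    for (ch in names(wild$contigs)) {
      cc <- wild$contigs[[ch]]
      L <- wild$contig_lengths[[ch]]
      for (i in seq_len(cfg$n_wild)) {
        hh <- self_pair(cc$H[2L * i - 1L, ], cc$H[2L * i, ], cc$pos, L,
                        cfg$crossover_rate, cfg$wild_selfing)
        wild_samples$contigs[[ch]]$H[2L * i - 1L, ] <- hh[[1]]
        wild_samples$contigs[[ch]]$H[2L * i, ] <- hh[[2]]
      }
    }
  }
  panels <- list(wild = wild_samples, crop = crop)
  group_of <- c(wild = "wild", crop = "crop")
  role_of <- c(wild = "wild", crop = "crop")
  tracts <- list()
  mode_tag <- c(dedomesticated = "weed_dd", introgressed = "weed_ix", f1 = "weed_f1")
  for (mode in names(cfg$n_weed)) {
    w <- simulate_weed(crop, wild, mode, cfg)
    tag <- mode_tag[[mode]]
    panels[[tag]] <- w$panel
    group_of[tag] <- tag
    role_of[tag] <- "weed"
    if (!is.null(w$tracts)) {
      w$tracts$sample <- sprintf("%s_%02d", tag, w$tracts$sample_idx)
      tracts[[tag]] <- w$tracts[, c("sample", "chrom", "start", "end", "origin")]
    }
  }
  # outgroup: fixed private differences, homozygous
  if (cfg$n_outgroup > 0) {
    occ <- lapply(names(cfg$contig_lengths), function(ch) {
      L <- cfg$contig_lengths[[ch]]
      used <- panels$crop$contigs[[ch]]$pos
      So <- stats::rpois(1, cfg$theta_outgroup * L)
      pos <- sort(setdiff(sample.int(L, min(So + length(used), L)), used)[seq_len(So)])
      pos <- pos[!is.na(pos)]
      list(pos = pos, H = matrix(1L, 2L * cfg$n_outgroup, length(pos)))
    })
    names(occ) <- names(cfg$contig_lengths)
    panels$outgroup <- new_hap_panel(occ, cfg$contig_lengths)
    group_of["outgroup"] <- "outgroup"
    role_of["outgroup"] <- "outgroup"
  }
  # sweeps act on the emitted group genotypes; because the sweep copies one
  # donor haplotype across the whole group, local ancestry inside the core is
  # rewritten to the donor's, and the truth tracts follow
  sweeps <- NULL
  if (!is.null(cfg$sweep_intervals) && nrow(cfg$sweep_intervals)) {
    for (s in seq_len(nrow(cfg$sweep_intervals))) {
      sw <- cfg$sweep_intervals[s, ]
      if (is.null(panels[[sw$group]]))
        stop("sweep target group not in cohort: ", sw$group)
      panels[[sw$group]] <- inject_sweep(panels[[sw$group]], sw$chrom,
                                         sw$start, sw$end, cfg$theta_wild,
                                         cfg$sweep_flank)
      if (!is.null(tracts[[sw$group]])) {
        st <- attr(panels[[sw$group]], "sweep_truth")
        donor_hap <- st$donor_hap[nrow(st)]
        donor_sample <- sprintf("%s_%02d", sw$group, ceiling(donor_hap / 2))
        tracts[[sw$group]] <- rewrite_tracts_for_sweep(
          tracts[[sw$group]], sw$chrom, sw$start, sw$end, donor_sample)
      }
    }
    sweeps <- cfg$sweep_intervals
  }
  # assemble the union site set
  counts <- vapply(panels, function(p) nrow(p$contigs[[1]]$H) / 2L, numeric(1))
  sample_ids <- unlist(lapply(names(panels), function(tag)
    sprintf("%s_%02d", tag, seq_len(counts[[tag]]))), use.names = FALSE)
  popmap <- data.frame(
    sample = sample_ids,
    group = rep(unname(group_of[names(panels)]), counts),
    role = rep(unname(role_of[names(panels)]), counts),
    stringsAsFactors = FALSE)
  geno_blocks <- list()
  sites <- NULL
  for (ch in names(cfg$contig_lengths)) {
    pos_union <- sort(unique(unlist(lapply(panels, function(p) p$contigs[[ch]]$pos))))
    block <- matrix(0L, length(sample_ids), length(pos_union))
    row0 <- 0L
    for (tag in names(panels)) {
      cc <- panels[[tag]]$contigs[[ch]]
      n <- nrow(cc$H) / 2L
      idx <- match(cc$pos, pos_union)
      g <- cc$H[seq(1, 2 * n, by = 2), , drop = FALSE] +
        cc$H[seq(2, 2 * n, by = 2), , drop = FALSE]
      block[row0 + seq_len(n), idx] <- g
      row0 <- row0 + n
    }
    geno_blocks[[ch]] <- block
    sites <- rbind(sites, data.frame(chrom = ch, pos = pos_union,
                                     stringsAsFactors = FALSE))
  }
  geno <- do.call(cbind, geno_blocks)
  ra <- assign_alleles(sites$pos)
  sites$ref <- ra$ref; sites$alt <- ra$alt
  gm <- geno_matrix(geno, sample_ids, sites)
  truth <- list(
    tracts = if (length(tracts)) do.call(rbind, c(tracts, make.row.names = FALSE)) else NULL,
    sweeps = sweeps,
    params = list(seed = cfg$seed, theta_wild = cfg$theta_wild,
                  contig_lengths = as.list(cfg$contig_lengths),
                  ancestral_allele = "ref",
                  crop_bottleneck_k = cfg$crop_bottleneck_k,
                  selfing_generations = cfg$selfing_generations,
                  introgression_fraction = cfg$introgression_fraction,
                  tract_length_mean = cfg$tract_length_mean))
  structure(list(gm = gm, popmap = popmap, truth = truth, cfg = cfg),
            class = "cohort")
}

#' Write a simulated cohort and its truth to disk
#'
#' Produces `cohort.vcf`, `popmap.tsv`, `truth_tracts.bed` (name column =
#' `sample|origin`), `truth_sweeps.bed` (name = target group) and
#' `truth_params.json` in `out_dir`.
#'
#' @param cfg A [scenario_config()].
#' @param out_dir Output directory (created if needed).
#' @return The `cohort` object, invisibly, with attribute `files`.
#' @export
emit_cohort <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  co <- simulate_cohort(cfg)
  files <- c(vcf = file.path(out_dir, "cohort.vcf"),
             popmap = file.path(out_dir, "popmap.tsv"),
             tracts = file.path(out_dir, "truth_tracts.bed"),
             sweeps = file.path(out_dir, "truth_sweeps.bed"),
             params = file.path(out_dir, "truth_params.json"))
  write_vcf(co$gm, files["vcf"], contig_lengths = cfg$contig_lengths)
  write_population_map(co$popmap, files["popmap"])
  if (!is.null(co$truth$tracts)) {
    tr <- co$truth$tracts
    write_bed(data.frame(chrom = tr$chrom, start = tr$start, end = tr$end,
                         name = paste(tr$sample, tr$origin, sep = "|")),
              files["tracts"])
  }
  if (!is.null(co$truth$sweeps)) {
    sw <- co$truth$sweeps
    write_bed(data.frame(chrom = sw$chrom, start = sw$start, end = sw$end,
                         name = sw$group), files["sweeps"])
  }
  jsonlite::write_json(co$truth$params, files["params"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  attr(co, "files") <- files
  invisible(co)
}

#' Base-pair Jaccard similarity of two interval sets
#'
#' Intervals are 0-based half-open data.frames with columns `chrom`, `start`,
#' `end`. Returns intersection width over union width.
#'
#' @param a,b Interval data.frames.
#' @return Numeric scalar in \[0, 1\] (1 if both sets are empty).
#' @export
interval_jaccard <- function(a, b) {
  as_gr <- function(x) {
    if (is.null(x) || nrow(x) == 0)
      return(GenomicRanges::GRanges())
    GenomicRanges::reduce(GenomicRanges::GRanges(
      x$chrom, IRanges::IRanges(x$start + 1, x$end)))
  }
  ga <- as_gr(a); gb <- as_gr(b)
  inter <- sum(as.numeric(GenomicRanges::width(GenomicRanges::intersect(ga, gb))))
  uni <- sum(as.numeric(GenomicRanges::width(GenomicRanges::union(ga, gb))))
  if (uni == 0) return(1)
  inter / uni
}
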