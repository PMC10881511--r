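# Private-SNP classification, windowed crop:wild ratios, chromosome painting
# and diagnostic domestication-locus genotyping.

#' Classify SNPs as crop-specific, wild-specific, shared or uninformative
#'
#' The alt allele is "present" in a panel when its copy count among
#' non-missing calls is at least `min_carriers`. A site is `crop_specific`
#' when present in the crop panel only, `wild_specific` when present in the
#' wild panel only, `shared` when present in both, and `uninformative` when
#' absent from both or when either panel's missing-call fraction exceeds
#' `max_missing_frac`.
#'
#' @param gm A [geno_matrix()].
#' @param crop_samples,wild_samples Disjoint, non-empty sample id vectors.
#' @param min_carriers Minimum alt copies for "presence" (default 1; a single
#'   miscall can flip a class, so the threshold is exposed).
#' @param max_missing_frac Maximum tolerated missing fraction per panel
#'   (default 0.2).
#' @return data.frame with the site table plus `crop_copies`, `wild_copies`
#'   and `class` (factor with the four levels).
#' @export
classify_private_snps <- function(gm, crop_samples, wild_samples,
                                  min_carriers = 1, max_missing_frac = 0.2) {
  if (!length(crop_samples) || !length(wild_samples)) stop("empty panel")
  if (length(intersect(crop_samples, wild_samples)))
    stop("crop and wild panels overlap")
  acC <- site_allele_counts(gm, crop_samples)
  acW <- site_allele_counts(gm, wild_samples)
  missC <- 1 - acC$n / (2 * length(crop_samples))
  missW <- 1 - acW$n / (2 * length(wild_samples))
  presC <- acC$j >= min_carriers
  presW <- acW$j >= min_carriers
  cls <- rep("uninformative", n_sites(gm))
  cls[presC & !presW] <- "crop_specific"
  cls[presW & !presC] <- "wild_specific"
  cls[presC & presW] <- "shared"
  cls[missC > max_missing_frac | missW > max_missing_frac] <- "uninformative"
  out <- gm$sites
  out$crop_copies <- acC$j
  out$wild_copies <- acW$j
  out$class <- factor(cls, levels = c("crop_specific", "wild_specific",
                                      "shared", "uninformative"))
  out
}

# alt copies carried by `samples` at the given site columns, per window
copies_by_window <- function(gm, samples, site_sel, widx, n_windows) {
  g <- gm$geno[samples, , drop = FALSE]
  g[g < 0L] <- 0L
  copies <- colSums(g)
  x <- numeric(n_sites(gm))
  x[site_sel] <- copies[site_sel]
  sum_by_window(x, widx, n_windows)
}

#' Windowed crop:wild private-allele ratio
#'
#' Per window, counts the alt-allele copies that the target samples carry at
#' crop-specific versus wild-specific sites, and the log ratio of the two
#' (default log2). Copies (het = 1, hom-alt = 2) rather than sites are
#' counted, so heterozygous recent hybrids contribute proportionally; set
#' `count_sites = TRUE` to count sites carrying at least one copy instead.
#' The log ratio is `NA` (window flagged undefined) when either count is 0.
#'
#' @param classes Output of [classify_private_snps()] on the same matrix.
#' @param gm A [geno_matrix()].
#' @param target_samples Samples whose alleles are counted (e.g. one weed
#'   strain).
#' @param windows Window table from [make_windows()].
#' @param log_base Base for the log ratio (default 2).
#' @param count_sites Count sites instead of allele copies (default FALSE).
#' @return `windows` plus `crop_copies`, `wild_copies`, `ratio`, `log_ratio`,
#'   `defined`.
#' @export
window_private_ratio <- function(classes, gm, target_samples, windows,
                                 log_base = 2, count_sites = FALSE) {
  stopifnot(nrow(classes) == n_sites(gm))
  widx <- window_of_sites(gm, windows)
  nw <- nrow(windows)
  g <- gm$geno[target_samples, , drop = FALSE]
  g[g < 0L] <- 0L
  if (count_sites) g <- (g > 0L) * 1L
  copies <- colSums(g)
  cs <- classes$class == "crop_specific"
  ws <- classes$class == "wild_specific"
  out <- windows
  out$crop_copies <- sum_by_window(ifelse(cs, copies, 0), widx, nw)
  out$wild_copies <- sum_by_window(ifelse(ws, copies, 0), widx, nw)
  out$defined <- out$crop_copies > 0 & out$wild_copies > 0
  out$ratio <- ifelse(out$defined, out$crop_copies / out$wild_copies, NA_real_)
  out$log_ratio <- ifelse(out$defined, log(out$ratio, base = log_base), NA_real_)
  out
}

#' Genome-wide private-allele totals per sample
#'
#' Total crop-specific and wild-specific alt copies carried by each sample,
#' with the crop:wild ratio. The genome-wide analogue of
#' [window_private_ratio()].
#'
#' @inheritParams window_private_ratio
#' @param samples Samples to tally (default: all).
#' @return data.frame `sample`, `crop_copies`, `wild_copies`, `ratio`.
#' @export
sample_private_totals <- function(classes, gm, samples = gm$sample_ids) {
  stopifnot(nrow(classes) == n_sites(gm))
  g <- gm$geno[samples, , drop = FALSE]
  g[g < 0L] <- 0L
  cs <- classes$class == "crop_specific"
  ws <- classes$class == "wild_specific"
  crop <- as.numeric(g %*% cs)
  wild <- as.numeric(g %*% ws)
  data.frame(sample = samples, crop_copies = crop, wild_copies = wild,
             ratio = ifelse(wild > 0, crop / wild,
                            ifelse(crop > 0, Inf, NA_real_)),
             row.names = NULL)
}

#' Paint a sample's chromosomes by local ancestry
#'
#' Per window, counts the crop-specific and wild-specific alt-allele copies
#' the target sample carries. With wild fraction
#' `f = wild / (wild + crop)`, the window is called `wild_like` when
#' `f >= wild_frac_threshold`, `crop_like` when `f <= 1 - wild_frac_threshold`,
#' `mixed` otherwise, and `undetermined` when fewer than `min_informative`
#' informative copies are present.
#'
#' @param classes Output of [classify_private_snps()].
#' @param gm A [geno_matrix()].
#' @param target_sample One sample id.
#' @param windows Window table from [make_windows()].
#' @param wild_frac_threshold Calling threshold (default 0.8).
#' @param min_informative Minimum informative copies per window (default 10).
#' @return `windows` plus `n_crop_copies`, `n_wild_copies`, `wild_frac`,
#'   `call` (factor crop_like/wild_like/mixed/undetermined); class
#'   `painting_track`.
#' @export
paint_chromosomes <- function(classes, gm, target_sample, windows,
                              wild_frac_threshold = 0.8, min_informative = 10) {
  if (!target_sample %in% gm$sample_ids)
    stop("unknown sample: ", target_sample)
  stopifnot(nrow(classes) == n_sites(gm))
  widx <- window_of_sites(gm, windows)
  nw <- nrow(windows)
  g <- gm$geno[target_sample, ]
  g[g < 0L] <- 0L
  cs <- classes$class == "crop_specific"
  ws <- classes$class == "wild_specific"
  out <- windows
  out$n_crop_copies <- sum_by_window(ifelse(cs, g, 0), widx, nw)
  out$n_wild_copies <- sum_by_window(ifelse(ws, g, 0), widx, nw)
  tot <- out$n_crop_copies + out$n_wild_copies
  out$wild_frac <- ifelse(tot > 0, out$n_wild_copies / tot, NA_real_)
  call <- rep("undetermined", nw)
  ok <- tot >= min_informative
  call[ok & out$wild_frac >= wild_frac_threshold] <- "wild_like"
  call[ok & out$wild_frac <= 1 - wild_frac_threshold] <- "crop_like"
  call[ok & out$wild_frac > 1 - wild_frac_threshold &
         out$wild_frac < wild_frac_threshold] <- "mixed"
  out$call <- factor(call, levels = c("crop_like", "wild_like", "mixed",
                                      "undetermined"))
  attr(out, "sample") <- target_sample
  class(out) <- c("painting_track", class(out))
  out
}

#' Merge adjacent same-call painting windows into blocks
#'
#' @param track Output of [paint_chromosomes()].
#' @param call Optional single call level to keep (e.g. `"wild_like"`).
#' @return data.frame `chrom`, `start`, `end`, `call` (BED-ready, 0-based
#'   half-open).
#' @export
painting_blocks <- function(track, call = NULL) {
  blocks <- list()
  for (ch in unique(track$chrom)) {
    t <- track[track$chrom == ch, ]
    t <- t[order(t$start), ]
    run <- rle(as.character(t$call))
    ends <- cumsum(run$lengths)
    starts <- ends - run$lengths + 1
    blocks[[ch]] <- data.frame(chrom = ch,
                               start = t$start[starts],
                               end = t$end[ends],
                               call = run$values,
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(blocks, make.row.names = FALSE))
  if (!is.null(call)) out <- out[out$call %in% call, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genotype diagnostic domestication loci
#'
#' Looks up each locus by (chrom, pos) in the matrix and calls each sample
#' `crop`, `wild`, `het` or `missing` according to which diagnostic allele it
#' carries; loci absent from the matrix, or whose crop/wild alleles do not
#' match the site's ref/alt pair, are called `absent` (with a warning for
#' allele mismatches).
#'
#' @param gm A [geno_matrix()].
#' @param loci data.frame with columns `gene`, `chrom`, `pos`, `crop_allele`,
#'   `wild_allele`.
#' @return data.frame in long form: `gene`, `chrom`, `pos`, `sample`, `call`.
#' @export
genotype_diagnostic_loci <- function(gm, loci) {
  stopifnot(all(c("gene", "chrom", "pos", "crop_allele", "wild_allele")
                %in% names(loci)))
  if (anyDuplicated(loci[, c("chrom", "pos")]))
    stop("duplicate locus rows in diagnostic table")
  if (any(loci$crop_allele == loci$wild_allele))
    stop("diagnostic alleles must differ")
  out <- list()
  key <- paste(gm$sites$chrom, gm$sites$pos)
  for (i in seq_len(nrow(loci))) {
    lc <- loci[i, ]
    idx <- match(paste(lc$chrom, lc$pos), key)
    if (is.na(idx)) {
      call <- rep("absent", length(gm$sample_ids))
    } else {
      ref <- gm$sites$ref[idx]; alt <- gm$sites$alt[idx]
      g <- gm$geno[, idx]
      if (lc$crop_allele == ref && lc$wild_allele == alt) {
        call <- c("missing", "crop", "het", "wild")[g + 2L]
      } else if (lc$crop_allele == alt && lc$wild_allele == ref) {
        call <- c("missing", "wild", "het", "crop")[g + 2L]
      } else {
        warning("diagnostic alleles at ", lc$gene,
                " do not match the site's ref/alt; reported absent")
        call <- rep("absent", length(gm$sample_ids))
      }
    }
    out[[i]] <- data.frame(gene = lc$gene, chrom = lc$chrom, pos = lc$pos,
                           sample = gm$sample_ids, call = call,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
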