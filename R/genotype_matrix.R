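# Genotype matrix container: samples x biallelic SNP sites.
# Genotype codes: 0 = hom-ref, 1 = het, 2 = hom-alt, -1 = missing.
# Site coordinates are 1-based (VCF convention); windows and BED intervals
# elsewhere in the package are 0-based half-open.

#' Construct a genotype matrix
#'
#' Bundles a samples x sites matrix of diploid genotype codes with per-site
#' metadata. Codes are 0 (hom-ref), 1 (het), 2 (hom-alt), -1 (missing). All
#' sites must be biallelic SNPs, sorted by (chrom, pos) with no duplicate
#' positions.
#'
#' @param geno Integer matrix, samples in rows, sites in columns.
#' @param sample_ids Character vector of unique sample names (row order).
#' @param sites data.frame with columns `chrom`, `pos` (1-based integer),
#'   `ref`, `alt` (single bases, different).
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(geno, sample_ids, sites) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(is.character(sample_ids), nrow(geno) == length(sample_ids))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
            ncol(geno) == nrow(sites))
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  sites$ref <- as.character(sites$ref)
  sites$alt <- as.character(sites$alt)
  if (nrow(sites) > 0) {
    bad <- nchar(sites$ref) != 1L | nchar(sites$alt) != 1L | sites$ref == sites$alt
    if (any(bad)) stop("all sites must be biallelic SNPs (single-base ref != alt)")
    o <- order(sites$chrom, sites$pos)
    if (any(o != seq_len(nrow(sites)))) {
      sites <- sites[o, , drop = FALSE]
      geno <- geno[, o, drop = FALSE]
    }
    if (anyDuplicated(sites[, c("chrom", "pos")])) stop("duplicate (chrom, pos) sites")
  }
  if (length(geno) && !all(geno %in% c(-1L, 0L, 1L, 2L)))
    stop("genotype codes must be in {-1, 0, 1, 2}")
  rownames(geno) <- sample_ids
  rownames(sites) <- NULL
  structure(list(geno = geno, sample_ids = sample_ids, sites = sites),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d sites on %d contig(s)\n",
              length(x$sample_ids), nrow(x$sites),
              length(unique(x$sites$chrom))))
  invisible(x)
}

#' Number of sites in a genotype matrix
#' @param gm A `geno_matrix`.
#' @return Integer site count.
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' Subset a genotype matrix
#'
#' @param gm A `geno_matrix`.
#' @param samples Optional character vector of sample ids to keep.
#' @param site_idx Optional integer vector of site (column) indices to keep.
#' @return A `geno_matrix`.
#' @export
subset_geno <- function(gm, samples = NULL, site_idx = NULL) {
  geno <- gm$geno
  ids <- gm$sample_ids
  sites <- gm$sites
  if (!is.null(samples)) {
    miss <- setdiff(samples, ids)
    if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
    geno <- geno[samples, , drop = FALSE]
    ids <- samples
  }
  if (!is.null(site_idx)) {
    geno <- geno[, site_idx, drop = FALSE]
    sites <- sites[site_idx, , drop = FALSE]
  }
  geno_matrix(geno, ids, sites)
}

# Per-site alt-allele copy count and allele sample size for a sample subset.
# Returns list(j = alt copies among non-missing calls, n = 2 * non-missing).
site_allele_counts <- function(gm, samples = NULL) {
  g <- if (is.null(samples)) gm$geno else {
    miss <- setdiff(samples, gm$sample_ids)
    if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
    gm$geno[samples, , drop = FALSE]
  }
  ok <- g >= 0L
  gpos <- g
  gpos[!ok] <- 0L
  list(j = colSums(gpos), n = 2L * colSums(ok),
       n_het = colSums(g == 1L))
}
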