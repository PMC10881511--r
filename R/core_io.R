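# Readers and writers for the standard formats the pipeline touches.
# Sites are 1-based (VCF convention); windows/BED are 0-based half-open.

GT_CODE <- c(
  "0/0" = 0L, "0|0" = 0L,
  "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
  "1/1" = 2L, "1|1" = 2L,
  "./." = -1L, ".|." = -1L, "." = -1L,
  "0/." = -1L, "./0" = -1L, "1/." = -1L, "./1" = -1L,
  "0|." = -1L, ".|0" = -1L, "1|." = -1L, ".|1" = -1L
)

#' Read a multi-sample VCF into a genotype matrix
#'
#' Keeps biallelic SNP records only (single-base REF and ALT, REF != ALT);
#' multiallelic and non-SNP records are dropped. Phased and unphased GT are
#' treated identically; half-calls (e.g. `0/.`) become missing; haploid GT
#' (`0`/`1`) is accepted as homozygous with a warning. Genotypes whose GQ or
#' DP fall below the optional thresholds are set missing, mirroring generic
#' per-genotype quality filtering of raw variant calls.
#'
#' @param path Path to a VCF 4.x file (plain or bgzipped).
#' @param region Optional `list(chrom, start, end)` (0-based half-open) to
#'   restrict sites.
#' @param min_gq,min_dp Optional numeric thresholds on FORMAT GQ / DP; a
#'   genotype with the field absent is kept.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path, region = NULL, min_gq = NULL, min_dp = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  n_meta <- length(vcf@meta)
  if (is.null(fix) || nrow(fix) == 0L) {
    ids <- colnames(vcf@gt)[-1]
    if (is.null(ids)) ids <- character(0)
    return(geno_matrix(matrix(integer(0), nrow = length(ids), ncol = 0),
                       ids,
                       data.frame(chrom = character(0), pos = integer(0),
                                  ref = character(0), alt = character(0))))
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") & ref != alt
  sites <- data.frame(chrom = fix[keep, "CHROM"],
                      pos = as.integer(fix[keep, "POS"]),
                      ref = ref[keep], alt = alt[keep],
                      stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")  # sites x samples
  gt <- gt[keep, , drop = FALSE]
  sample_ids <- colnames(gt)
  tok <- as.vector(gt)
  tok[is.na(tok)] <- "."
  code <- GT_CODE[tok]
  if (anyNA(code)) {
    hap <- tok %in% c("0", "1")
    if (any(hap & is.na(code))) {
      warning("haploid GT calls treated as homozygous diploid")
      code[is.na(code) & tok == "0"] <- 0L
      code[is.na(code) & tok == "1"] <- 2L
    }
    if (anyNA(code)) {
      bad <- which(is.na(code))[1]
      rec <- (bad - 1L) %% nrow(gt) + 1L
      line <- n_meta + 1L + which(keep)[rec]
      stop(sprintf("malformed GT token '%s' at VCF line %d", tok[bad], line))
    }
  }
  code <- matrix(code, nrow = nrow(gt), ncol = ncol(gt))
  mask_below <- function(code, field, thr) {
    if (is.null(thr)) return(code)
    val <- suppressWarnings(vcfR::extract.gt(vcf, element = field, as.numeric = TRUE))
    if (is.null(val)) return(code)
    val <- val[keep, , drop = FALSE]
    code[!is.na(val) & val < thr] <- -1L
    code
  }
  code <- mask_below(code, "GQ", min_gq)
  code <- mask_below(code, "DP", min_dp)
  geno <- t(code)
  if (!is.null(region)) {
    in_r <- sites$chrom == region[[1]] & sites$pos > region[[2]] & sites$pos <= region[[3]]
    geno <- geno[, in_r, drop = FALSE]
    sites <- sites[in_r, , drop = FALSE]
  }
  dup <- duplicated(sites[, c("chrom", "pos")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (chrom, pos) record(s) dropped (first kept)")
    geno <- geno[, !dup, drop = FALSE]
    sites <- sites[!dup, , drop = FALSE]
  }
  geno_matrix(geno, sample_ids, sites)
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits a GT-only FORMAT; codes map 0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`,
#' -1 -> `./.`.
#'
#' @param gm A [geno_matrix()].
#' @param path Output path.
#' @param contig_lengths Optional named vector of contig lengths for
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=feralscan",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", gm$sample_ids), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (n_sites(gm) > 0) {
    gt_str <- c(`-1` = "./.", `0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- matrix(gt_str[as.character(gm$geno)], nrow = nrow(gm$geno))
    body <- paste(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref, gm$sites$alt,
                  ".", ".", ".", "GT", sep = "\t")
    sample_cols <- do.call(paste, c(lapply(seq_len(nrow(gt)), function(i) gt[i, ]),
                                    sep = "\t"))
    writeLines(paste(body, sample_cols, sep = "\t"), con)
  }
  invisible(path)
}

#' Tile contigs with fixed-size non-overlapping windows
#'
#' Windows are 0-based half-open and tile each contig from 0; the last window
#' of a contig may be short.
#'
#' @param contig_lengths Named numeric vector, contig -> length in bp.
#' @param size Window size in bp (default 100 kb).
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
make_windows <- function(contig_lengths, size = 1e5) {
  if (size <= 0) stop("window size must be > 0")
  stopifnot(!is.null(names(contig_lengths)), all(contig_lengths > 0))
  out <- lapply(names(contig_lengths), function(ch) {
    len <- contig_lengths[[ch]]
    starts <- seq(0, len - 1, by = size)
    data.frame(chrom = ch, start = starts, end = pmin(starts + size, len))
  })
  do.call(rbind, out)
}

# Map each site of gm to its window row index (NA if outside all windows).
# Windows must be the non-overlapping output of make_windows.
window_of_sites <- function(gm, windows) {
  idx <- rep(NA_integer_, n_sites(gm))
  for (ch in unique(gm$sites$chrom)) {
    w <- which(windows$chrom == ch)
    if (!length(w)) next
    s <- which(gm$sites$chrom == ch)
    # site pos is 1-based; window [start, end) half-open 0-based
    k <- findInterval(gm$sites$pos[s] - 1L, windows$start[w])
    ok <- k >= 1 & (gm$sites$pos[s] - 1L) < windows$end[w][pmax(k, 1)]
    idx[s[ok]] <- w[k[ok]]
  }
  idx
}

#' Read a population map
#'
#' Expects a TSV with header columns `sample`, `group`, `role`; roles are from
#' the closed set wild / crop / weed / outgroup.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `sample`, `group`, `role`.
#' @export
read_population_map <- function(path) {
  pm <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "group", "role") %in% names(pm)))
  if (anyDuplicated(pm$sample))
    stop("duplicate sample in population map: ",
         paste(unique(pm$sample[duplicated(pm$sample)]), collapse = ", "))
  bad <- setdiff(unique(pm$role), c("wild", "crop", "weed", "outgroup"))
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  pm[, c("sample", "group", "role")]
}

#' Write a population map TSV
#' @param popmap data.frame with columns `sample`, `group`, `role`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population_map <- function(popmap, path) {
  utils::write.table(popmap[, c("sample", "group", "role")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene intervals from a GFF3 file
#'
#' Returns `gene`-type features as 0-based half-open intervals.
#'
#' @param path Path to a GFF3 file.
#' @return data.frame with columns `chrom`, `start`, `end`, `gene`.
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  id <- if (!is.null(gr$ID)) gr$ID else gr$Name
  if (is.null(id)) id <- paste0("gene", seq_along(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             gene = as.character(id),
             stringsAsFactors = FALSE)
}

#' Read / write BED intervals
#'
#' BED is 0-based half-open; intervals are returned/accepted as data.frames
#' with columns `chrom`, `start`, `end` and optional `name`.
#'
#' @param path BED file path.
#' @return data.frame of intervals.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  if (!is.null(gr$name)) out$name <- gr$name
  out
}

#' @rdname read_bed
#' @param intervals data.frame with columns `chrom`, `start`, `end`,
#'   optionally `name` (0-based half-open).
#' @export
write_bed <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(start = intervals$start + 1L, end = intervals$end))
  if (!is.null(intervals$name)) gr$name <- intervals$name
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
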