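# Cross-strain overlap of candidate windows and gene-annotation intersection.

#' Candidate windows shared across strains
#'
#' Windows are compared by identity (same tiling across strains); a window is
#' reported when it is a candidate in at least `min_strains` of the input
#' sets, with the supporting strain list.
#'
#' @param sets Named list (strain -> data.frame with `chrom`, `start`, `end`,
#'   e.g. candidate rows of [pi_ratio_scan()] output).
#' @param min_strains Minimum supporting strains (default 2).
#' @return data.frame `chrom`, `start`, `end`, `n_strains`, `strains`
#'   (comma-separated), sorted by position.
#' @export
overlap_candidates <- function(sets, min_strains = 2) {
  if (length(sets) < 2) stop("need at least 2 candidate sets")
  if (min_strains > length(sets))
    stop("min_strains exceeds the number of sets")
  if (is.null(names(sets))) names(sets) <- paste0("strain", seq_along(sets))
  ids <- lapply(sets, function(s) paste(s$chrom, s$start, s$end, sep = ":"))
  all_ids <- unique(unlist(ids))
  member <- vapply(ids, function(x) all_ids %in% x, logical(length(all_ids)))
  if (is.null(dim(member))) member <- matrix(member, nrow = length(all_ids))
  nsup <- rowSums(member)
  keep <- nsup >= min_strains
  if (!any(keep))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_strains = integer(0),
                      strains = character(0)))
  parts <- do.call(rbind, strsplit(all_ids[keep], ":", fixed = TRUE))
  out <- data.frame(chrom = parts[, 1],
                    start = as.numeric(parts[, 2]),
                    end = as.numeric(parts[, 3]),
                    n_strains = as.integer(nsup[keep]),
                    strains = apply(member[keep, , drop = FALSE], 1, function(m)
                      paste(names(sets)[m], collapse = ",")),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Genes overlapping candidate regions
#'
#' Reports genes overlapping any region by at least 1 bp under half-open
#' interval intersection, deduplicated and sorted, with the overlap
#' coordinates.
#'
#' @param regions data.frame `chrom`, `start`, `end` (0-based half-open).
#' @param genes data.frame `chrom`, `start`, `end`, `gene` (0-based
#'   half-open), e.g. from [read_gff3_genes()].
#' @return data.frame `gene`, `chrom`, `start`, `end`, `overlap_start`,
#'   `overlap_end`.
#' @export
genes_in_regions <- function(regions, genes) {
  if (!nrow(regions) || !nrow(genes))
    return(data.frame(gene = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      overlap_start = numeric(0), overlap_end = numeric(0)))
  if (!any(genes$chrom %in% regions$chrom)) {
    warning("no shared chromosome names between regions and genes")
    return(data.frame(gene = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      overlap_start = numeric(0), overlap_end = numeric(0)))
  }
  gr_r <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start + 1, regions$end))
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1, genes$end))
  hits <- GenomicRanges::findOverlaps(gr_g, gr_r)
  if (!length(hits))
    return(data.frame(gene = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      overlap_start = numeric(0), overlap_end = numeric(0)))
  gi <- S4Vectors::queryHits(hits)
  ri <- S4Vectors::subjectHits(hits)
  ov_start <- pmax(genes$start[gi], regions$start[ri])
  ov_end <- pmin(genes$end[gi], regions$end[ri])
  out <- data.frame(gene = genes$gene[gi], chrom = genes$chrom[gi],
                    start = genes$start[gi], end = genes$end[gi],
                    overlap_start = ov_start, overlap_end = ov_end,
                    stringsAsFactors = FALSE)
  # deduplicate genes hit by several regions: keep widest merged overlap span
  out <- out[order(out$chrom, out$start, out$overlap_start), , drop = FALSE]
  dup <- duplicated(out$gene)
  if (any(dup)) {
    agg_s <- tapply(out$overlap_start, out$gene, min)
    agg_e <- tapply(out$overlap_end, out$gene, max)
    out <- out[!dup, , drop = FALSE]
    out$overlap_start <- as.numeric(agg_s[out$gene])
    out$overlap_end <- as.numeric(agg_e[out$gene])
  }
  rownames(out) <- NULL
  out
}
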