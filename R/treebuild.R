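# Distance-based phylogeny of all accessions: homozygous complete-data SNPs,
# p / Jukes-Cantor distances, neighbor-joining (ape), site bootstrap,
# outgroup rooting, Newick output.

#' Select tree-suitable sites
#'
#' Retains sites where every sample is homozygous (code 0 or 2) with no
#' missing data, the standard filter for concatenated SNP phylogenies of
#' selfing accessions.
#'
#' @param gm A [geno_matrix()].
#' @return A filtered [geno_matrix()].
#' @export
select_tree_sites <- function(gm) {
  keep <- colSums(gm$geno == 0L | gm$geno == 2L) == nrow(gm$geno)
  if (!any(keep))
    stop("no homozygous complete-data site retained; check input (highly ",
         "heterozygous or missing-rich matrices cannot be used)")
  subset_geno(gm, site_idx = which(keep))
}

#' Pairwise distances from a homozygous SNP matrix
#'
#' `p` is the mismatch fraction over retained sites (one base per sample per
#' site); `jc` applies the Jukes-Cantor correction
#' `-(3/4) ln(1 - 4p/3)`. Pairs with `p >= 3/4` are undefined under `jc` and
#' returned as `NA` with a warning.
#'
#' @param gm A [geno_matrix()] of homozygous complete-data sites
#'   (see [select_tree_sites()]).
#' @param model `"jc"` (default) or `"p"`.
#' @return Symmetric distance matrix with zero diagonal, labels = sample ids.
#' @export
pairwise_distance <- function(gm, model = c("jc", "p")) {
  model <- match.arg(model)
  if (any(gm$geno == 1L | gm$geno < 0L))
    stop("matrix contains heterozygous or missing calls; run select_tree_sites()")
  X <- gm$geno / 2  # 0/1 alleles
  S <- ncol(X)
  if (S == 0) stop("no sites")
  cross <- X %*% t(1 - X)
  mism <- cross + t(cross)
  p <- mism / S
  d <- p
  if (model == "jc") {
    bad <- p >= 0.75
    if (any(bad[upper.tri(bad)])) {
      warning("p-distance >= 3/4 for some pair(s); JC distance undefined (NA)")
      d[bad] <- NA_real_
    }
    ok <- !bad
    d[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  }
  diag(d) <- 0
  dimnames(d) <- list(gm$sample_ids, gm$sample_ids)
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on a distance matrix; negative branch lengths are
#' clamped to zero with the deficit moved to the adjacent edge (standard
#' practice). Additive distance matrices are recovered exactly.
#'
#' @param dm Symmetric distance matrix with labels.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (nrow(dm) < 3) stop("need at least 3 labels")
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix not symmetric")
  tr <- ape::nj(dm)
  neg <- tr$edge.length < 0
  if (any(neg)) {
    # move the deficit to the sister edge sharing the child node
    for (e in which(neg)) {
      deficit <- tr$edge.length[e]
      tr$edge.length[e] <- 0
      sib <- which(tr$edge[, 1] == tr$edge[e, 1] & seq_along(neg) != e)
      if (length(sib)) tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + deficit
    }
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

# canonical bipartition strings for every internal node of a tree: the side
# of each internal edge not containing the alphabetically first tip, as a
# sorted "|"-joined label string (comparable across unrooted topologies)
tree_bipartitions <- function(tree) {
  pp <- ape::prop.part(tree)
  ref <- min(tree$tip.label)
  vapply(pp, function(idx) {
    tips <- tree$tip.label[idx]
    if (ref %in% tips) tips <- setdiff(tree$tip.label, tips)
    paste(sort(tips), collapse = "|")
  }, character(1))
}

#' Site-bootstrap support for an NJ tree
#'
#' Resamples sites with replacement `B` times, rebuilds the NJ tree each time,
#' and reports for each internal edge of the original tree the percentage of
#' replicates whose tree contains the same bipartition (stored in
#' `node.label`; the full per-replicate bipartition sets are kept in the
#' `boot_bipartitions` attribute so supports can be looked up after rooting,
#' see [clade_support()]).
#'
#' @param gm Homozygous complete-data [geno_matrix()]
#'   (see [select_tree_sites()]).
#' @param B Bootstrap replicates (default 100).
#' @param seed Optional integer seed for reproducible resampling.
#' @param model Distance model passed to [pairwise_distance()].
#' @return The NJ `phylo` tree with bootstrap percentages as `node.label`.
#' @export
bootstrap_support <- function(gm, B = 100, seed = NULL, model = "jc") {
  if (B < 1) stop("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  X <- gm$geno / 2
  ids <- gm$sample_ids
  build <- function(x) {
    S <- ncol(x)
    cross <- x %*% t(1 - x)
    p <- (cross + t(cross)) / S
    d <- if (model == "jc") {
      pc <- pmin(p, 0.7499999)
      -0.75 * log(1 - 4 * pc / 3)
    } else p
    dimnames(d) <- list(ids, ids)
    ape::nj(d)
  }
  phy <- nj_tree(pairwise_distance(gm, model))
  boot <- lapply(seq_len(B), function(i)
    tree_bipartitions(build(X[, sample.int(ncol(X), replace = TRUE),
                              drop = FALSE])))
  base_bip <- tree_bipartitions(phy)
  counts <- vapply(base_bip, function(bp)
    sum(vapply(boot, function(s) bp %in% s, logical(1))), numeric(1))
  phy$node.label <- round(100 * counts / B)
  attr(phy, "boot_bipartitions") <- boot
  phy
}

#' Root a tree on an outgroup
#'
#' Places the root on the edge separating the (required monophyletic)
#' outgroup from the ingroup. Total tree length is preserved.
#'
#' @param tree A `phylo` tree.
#' @param outgroup_samples Leaf labels of the outgroup.
#' @return A rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup_samples) {
  miss <- setdiff(outgroup_samples, tree$tip.label)
  if (length(miss)) stop("outgroup leaves not in tree: ",
                         paste(miss, collapse = ", "))
  if (length(outgroup_samples) > 1 &&
      !ape::is.monophyletic(tree, outgroup_samples))
    stop("outgroup is not monophyletic in the unrooted tree: ",
         paste(outgroup_samples, collapse = ", "))
  ape::root(tree, outgroup = outgroup_samples, resolve.root = TRUE)
}

#' Write / read Newick trees
#'
#' Thin wrappers over `ape::write.tree` / `ape::read.tree`, emitting branch
#' lengths and any bootstrap node labels.
#'
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @return `path` invisibly (write) or a `phylo` tree (read).
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Bootstrap support of the smallest clade containing a sample set
#'
#' Finds the MRCA of `samples` in `tree` (typically the rooted tree) and
#' returns the clade's tip set together with its bootstrap support, computed
#' by counting the clade's bipartition among the bootstrap replicates of
#' `boot` (a tree from [bootstrap_support()], whose `boot_bipartitions`
#' attribute survives rooting-induced node renumbering).
#'
#' @param tree A `phylo` tree (e.g. rooted).
#' @param samples Leaf labels.
#' @param boot Tree returned by [bootstrap_support()]; defaults to `tree`.
#' @return List with `tips` (clade leaf labels) and `support` (percent).
#' @export
clade_support <- function(tree, samples, boot = tree) {
  node <- ape::getMRCA(tree, samples)
  tips <- if (is.null(node)) tree$tip.label
          else ape::extract.clade(tree, node)$tip.label
  sets <- attr(boot, "boot_bipartitions")
  if (is.null(sets)) stop("boot tree lacks bootstrap bipartitions; ",
                          "use bootstrap_support()")
  side <- sort(tips)
  if (min(tree$tip.label) %in% side)
    side <- sort(setdiff(tree$tip.label, tips))
  bp <- paste(side, collapse = "|")
  sup <- 100 * mean(vapply(sets, function(s) bp %in% s, logical(1)))
  list(tips = tips, support = sup)
}
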