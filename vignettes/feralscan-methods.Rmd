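---
title: "Methods: detecting wild introgression and de-domestication in weedy crop genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting wild introgression and de-domestication in weedy crop genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Weedy (feral) forms of crops arise in two main ways: *de-domestication*, in
which a weed descends directly from the cultivated gene pool, and
*hybridization/introgression*, in which crosses with a wild relative inject
wild haplotype blocks — often carrying weediness traits such as seed
shattering, awns and dormancy — into a crop genetic background. Recent
hybrids are also recognizable directly, because predominantly selfing
populations are highly homozygous and an outcrossed individual is not.

`feralscan` implements the population-genomic scans used to distinguish these
origins from a multi-sample SNP matrix (VCF), and ships a cohort simulator
with exact ancestry truth so that every scan can be validated end to end.

# The genotype model

All analyses operate on diploid biallelic SNP genotypes coded 0 (hom-ref), 1
(het), 2 (hom-alt), -1 (missing). Only biallelic SNPs are retained at the VCF
boundary; per-genotype quality thresholds (GQ, DP) can be applied at read
time, mirroring the genotype-level filtering used on raw variant calls.
Site coordinates are 1-based (VCF convention); windows and BED intervals are
0-based half-open. Window scans use non-overlapping 100-kb windows by default
and divide by the full window length, the convention of VCFtools-style scans
(an accessibility mask can be emulated by adjusting window sizes; this is out
of scope here).

# Statistics

**Nucleotide diversity.** Per site with `j` alt alleles among `n` non-missing
alleles, the unbiased pairwise diversity is `2 j (n - j) / (n (n - 1))`;
window pi sums this over SNPs and divides by window length. **Watterson's
theta** is `S / (a_{n-1} L)` with `S` segregating sites and
`a_{n-1} = sum_{i<n} 1/i`. Because missing data make `n` vary by site, pi
uses the per-site `n` while theta uses the window median allele count in the
harmonic number; both choices are documented here because the window value is
otherwise convention-dependent.

**Heterozygosity rate** of an individual is the proportion of its non-missing
variant genotypes (codes 1 or 2) that are heterozygous. Under selfing this
halves each generation, so a rate an order of magnitude above the population
median flags a recent outcross.

**F_ST** is the Weir–Cockerham (1984) two-population estimator; per-site
variance components a, b, c are summed over the window and the window value
is `sum(a) / sum(a+b+c)` (ratio of sums, not mean of ratios — the standard,
stable aggregation). Sites monomorphic across both populations are skipped;
the estimator may be slightly negative at weak differentiation.

**Private-SNP classification.** A site's alt allele is *present* in a panel
when its copy count is at least `min_carriers` (default 1: "detected" means a
single allele copy; the threshold is exposed because one miscall can flip a
class). Sites are crop-specific, wild-specific, shared, or uninformative
(absent from both panels, or panel missingness above `max_missing_frac`,
default 0.2). The crop:wild private-allele ratio counts allele copies
(het = 1, hom = 2) rather than sites so that heterozygous recent hybrids
contribute proportionally; a `count_sites` switch restores site counting.
Log-ratios use base 2.

**Chromosome painting.** Per 100-kb window and target sample, the wild
fraction `f = wild_copies / (wild_copies + crop_copies)` over panel-specific
alleles calls the window wild-like (`f >= 0.8`), crop-like (`f <= 0.2`),
mixed, or undetermined (fewer than 10 informative copies). The thresholds are
validated empirically: on simulated introgressed weeds the called wild-like
blocks recover the true tracts with median Jaccard well above 0.8, and
de-domesticated controls call zero wild-like bases. No HMM smoothing is
applied; window-level voting is the intended granularity of the scan.

**Pi-ratio (LNDR) scan.** Windows are ranked by `pi_crop / pi_weed`; the top
5% of *eligible* windows (at least `min_snps = 10` segregating sites per
group and `pi_weed > 0`) are sweep candidates, ties included. The SNP floor
guards a known artifact: without it the top of the list is dominated by
near-empty windows.

**CLR sweep scan.** The composite likelihood ratio compares, at each of 2,000
evaluation positions per chromosome (grid semantics, as in SweeD), a
sweep-distorted site frequency spectrum against the genome-wide background
SFS. The sweep model is the star-like approximation: a lineage at distance
`d` bp escapes the sweep with probability `p_e = 1 - exp(-lam d)`; the
`B ~ Binomial(n, p_e)` escaped lineages plus one ancestor of the trapped
lineages draw their derived-allele configuration from the background SFS
(hypergeometric projection), and the trapped lineages inherit their
ancestor's state. Likelihoods condition on polymorphism. `CLR = 2 max_lam
sum_sites [ln P_sweep - ln P_bg]`, floored at zero because the background
(`p_e = 1`) is always admissible — so CLR is nonnegative by construction.

Numerical choices: the lam grid is 20 log-spaced escape intensities from
1e-6/bp to `-ln(0.01)/1e4` (p_e = 0.99 at 10 kb); sites with `p_e > 0.9999`
contribute equally to both models and are skipped. For speed the scan bins
sites into 48 log-spaced shells of `s = lam d` and uses the exact model
probability at each shell's geometric midpoint; the per-site probability
function itself (`sweep_site_prob`) is exact and is what the tests check
against exhaustive enumeration. The folded spectrum is the default for real
data (no polarization is performed); unfolded mode is used on simulated data,
where the ancestral allele is the reference by construction. Sites whose
allele sample size differs from the modal complete count are excluded from
the scan; the background SFS instead projects such sites down
hypergeometrically.

**Phylogeny.** The NJ tree uses sites homozygous and complete in every
sample, one base per sample per site. Distances are Jukes–Cantor-corrected
mismatch fractions by default (plain p-distance optional). The maximum
composite likelihood distance of MEGA is deliberately not reimplemented: on
biallelic SNP matrices the topology is driven by mismatch fractions, and the
JC correction is monotone in them. Bootstrap support resamples sites with
replacement (default B = 100) and
counts canonical bipartitions of each replicate tree; supports are therefore
well-defined after outgroup rooting. Negative NJ branch lengths are clamped
to zero with the deficit moved to the adjacent edge.

**Candidate overlap.** Shared candidates are windows with identical IDs
across strains (all strains are scanned on one tiling); genes intersect
candidate regions under half-open interval semantics with at least 1 bp of
overlap.

# The simulator

The generator is a mosaic/copying model, not a coalescent: tract truth is
exact and cohorts take seconds. It emulates the statistical structure the
scans rely on, in this order:

1. **Wild panel.** Segregating sites are a Poisson process with expectation
   `theta_wild a_{2n-1} L`; derived counts follow the neutral spectrum
   `P(i) ∝ 1/i`; the reference allele is ancestral. This makes Watterson's
   estimator unbiased by construction, which the calibration test exploits.
   Emitted wild *samples* are partially inbred (`wild_selfing = 2`
   generations), reflecting the mixed mating system of wild rice; the
   haplotype pool itself is untouched and supplies founders and donors.
2. **Crop.** `crop_bottleneck_k = 8` founder haplotypes are drawn from the
   pool; a fraction `bottleneck_fixation = 0.4` of founder-polymorphic sites
   is driven to fixation (frequency-weighted choice of the surviving allele),
   modeling drift and selection during domestication — without this step a
   founder subsample preserves expected pairwise diversity and the documented
   crop diversity loss cannot arise. Crop-lineage private mutations
   (`theta_crop_mut = 0.001`/bp) are added on the founders, individuals are
   recombinant founder mosaics (1 crossover / 10 Mb / gamete), and
   `selfing_generations = 10` of selfing make the crop inbred lines.
3. **Weeds.** De-domesticated weeds are outcrossed crop draws followed by
   selfing; introgressed weeds carry exponential wild tracts (mean 1 Mb,
   pasted on both haplotypes from two independent pool haplotypes, then
   selfed) covering 20% of the genome in expectation, tract starts drawn
   stationarily so coverage is unbiased at contig edges; F1 hybrids are one
   crop gamete plus one wild gamete, unselfed. Ancestry tracts are recorded
   for the selfed weeds; F1 ancestry is heterozygous genome-wide, so a
   single-origin tiling does not apply and F1s carry no tract records.
4. **Sweeps.** Inside each configured interval all target-group haplotypes
   are replaced by one donor haplotype; a Poisson(`theta L_core / 10`)
   sprinkle of new singletons restores a trace of diversity (keeping windows
   eligible for the pi-ratio scan, as real sweeps retain post-sweep
   mutations); diversity recovers over a 50-kb flank via per-haplotype
   uniform escape breakpoints, emulating recombinational escape. Because the
   sweep copies one haplotype group-wide, local ancestry in the core is
   rewritten to the donor's, and the truth tracts are updated accordingly
   (the partially copied flanks are left as-is; their ancestry is genuinely
   mixed).
5. **Outgroup.** One accession homozygous for `theta_outgroup = 0.001`/bp
   private fixed differences, used only for rooting. The value is kept small
   deliberately: the homozygous-complete tree filter enriches for
   outgroup-private sites, and a larger divergence saturates the
   outgroup distances (p >= 3/4 breaks the JC transform).

All randomness flows through R's default Mersenne-Twister stream seeded once
per cohort, so cohorts are byte-identical under a fixed seed.

## Default study conditions

The default scenario is a scaled-down analogue of a resequencing cohort: 16
wild, 16 crop, 10 de-domesticated weeds, 10 introgressed weeds, 4 F1s, one
outgroup, on two contigs (4 Mb + 2 Mb) at `theta_wild = 0.005`/bp, with one
200-kb sweep per weed strain (chr1:2.5–2.7 Mb in the de-domesticated strain,
chr2:0.6–0.8 Mb in the introgressed strain; at this genome scale a wider
sweep would occupy more windows than the top-5% candidate list can hold). Problem sizes in the tests (and
the acceptance script) follow these defaults; the sweep-localization
benchmark uses a dedicated 10-sample wild panel on a 5-Mb chromosome with a
200-kb central sweep, scanned on a 2,000-point grid, and its false-positive
control uses 1-Mb neutral chromosomes against a 100-permutation positional
null.

## What the simulator does and does not emulate

It reproduces: realistic diversity contrasts (wild > crop > selfed weed),
private-allele structure between panels, block-wise local ancestry with exact
truth, selfing-driven homozygosity and its F1 contrast, sweep-shaped local
SFS distortion, and a rootable phylogeny. It does **not** model: genealogical
correlation (no coalescent tree; linkage exists only through founder mosaics
and tracts), recombination-rate or mutation-rate heterogeneity, gene
conversion, sequencing error or missingness (tests add missingness
synthetically), background selection, or population structure within panels.
Passing tests therefore demonstrate correctness of the estimators and the
recoverability of planted signals under the stated model — not performance on
any particular real dataset.

# Analysis-level choices

* **F1 exclusion from the tree.** A concatenated-SNP NJ tree is built from
  homozygous complete-data sites. A genome-wide heterozygote is het at
  exactly the fixed crop/wild differences, so keeping F1s deletes every
  diagnostic character from the matrix — the filter's assumptions simply do
  not hold for them. The tree stage therefore drops genome-wide
  heterozygotes and reports them separately (their status is established by
  the heterozygosity scan). Bootstrap support for the crop clade is assessed
  on the crop, de-domesticated, wild and outgroup accessions; introgressed
  mosaics legitimately attach at intermediate positions and are assessed by
  placement, not support.
* **Degenerate inputs.** Windows without usable sites give 0 for pi/theta
  (no segregation) and NA for F_ST and pi-ratio; `pi_weed = 0` windows are
  ineligible rather than infinite; painting windows below the informative
  floor are `undetermined`; JC distances are NA at `p >= 3/4` with a warning.
* **Determinism.** Every stochastic entry point takes or derives from an
  integer seed; scans are deterministic given the data.

# Known limitations

The CLR scan's shell binning trades a negligible likelihood error for a
large constant-factor speedup; `n_shells` can be raised if exactness at the
scan level matters. The painting classifier is window-granular (no
sub-window breakpoints). The simulator's independence across sites makes
bootstrap supports optimistic relative to linked real data. Cross-reference
VCF merging, imputation, INDELs and BAM-level processing are out of scope at
the package boundary.
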