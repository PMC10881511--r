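Package: feralscan
Title: Population-Genomic Scans for Wild Introgression and De-Domestication in Weedy Crop Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects wild-relative introgression and de-domestication signals in
    feral (weedy) crop populations from multi-sample SNP genotype data. Implements
    private-allele classification and chromosome painting, windowed nucleotide
    diversity (pi, Watterson's theta), per-individual heterozygosity rates,
    Weir-Cockerham F_ST, pi-ratio (low-nucleotide-diversity-region) selection
    scans, a SweepFinder-style composite likelihood ratio sweep scan on a
    per-chromosome grid, diagnostic domestication-locus genotyping,
    neighbor-joining phylogenies with bootstrap support, and candidate-window
    overlap with gene annotations. Ships a mosaic crop/wild/weed cohort simulator
    with machine-readable truth (ancestry tracts, sweep intervals) so every scan
    can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
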