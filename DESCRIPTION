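Package: ecoscan
Title: Population-Genomic Analysis of Ecotype Differentiation and
    Inversion Supergenes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and characterising genetically distinct
    ecotypes from multi-sample SNP genotype data: per-population allele
    frequencies with coverage filtering, delta-allele-frequency genome
    scans and cutoff heatmaps, chi-square association scans with
    Bonferroni correction, PCA and K-means clustering, consensus-haplotype
    genotyping of chromosomal inversions (supergenes) with recombinant
    segment detection, nucleotide diversity (Watterson's theta, pi),
    Tajima's D, effective population size, Reynolds-type coancestry FST in
    windows and genome-wide, UPGMA and neighbor-joining population trees,
    and likelihood-based population assignment from pooled allele
    frequencies. Includes a synthetic-data generator (drifted populations,
    adaptive loci, inversion blocks with recombinant haplotypes) with full
    ground-truth tables so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
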