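Package: invscan
Title: Detection and Genotyping of Polymorphic Chromosome Inversions from SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects polymorphic chromosome inversions from biallelic SNP
    genotype matrices, as obtained from imputed low-coverage whole-genome
    sequencing. Combines a per-chromosome principal component analysis with a
    sliding-window scan of SNP loading variance, identity-by-state clustering
    of samples into AA/AB/BB inversion karyotypes via multidimensional scaling
    and fuzzy c-means, an association-based estimate of inversion coordinates,
    and short-range linkage-disequilibrium corroboration. Includes marker
    filtering with windowed LD pruning, pairwise dependence tests between
    detected inversions, and a genotype-level simulator of inversion
    polymorphisms with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
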