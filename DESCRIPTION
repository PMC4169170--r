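Package: biofilmq
Title: Quantification and Analysis of Yeast Biofilm-Related Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies biofilm-related phenotypes of Saccharomyces natural
    isolates from assay photographs and plate-reader tables: the settling
    (flocculation) ratio from intensity plot-profiles along a tube axis, the
    background-corrected mean gray intensity of washed agar-invasion spots,
    and crystal-violet polystyrene adhesion from OD570 readings. Provides the
    downstream statistical layer (Kendall tau-b rank correlation on ordinal
    0-5 scores, Welch two-sample comparisons of haploid versus diploid
    replicates with Benjamini-Hochberg false-discovery-rate classification,
    ordinary least-squares fits), per-phenotype linear normalization to a 0-5
    scale, equal-width binning, and Euclidean-distance hierarchical clustering
    of strain phenotype vectors with Cluster/TreeView-compatible (CDT/GTR) and
    Newick output. Includes synthetic generators for tube images, invasion
    spots and multi-strain phenotype panels with known ground truth so every
    pipeline stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    tiff,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
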