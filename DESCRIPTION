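Package: floregion
Title: Phylogeny-Informed Floristic Regionalization from Presence-Absence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delineates floristic regions from a site-by-taxon
    presence-absence matrix and a dated phylogeny. Computes taxonomic and
    phylogenetic turnover (Simpson and Jaccard turnover components, the
    latter on shared root-anchored branch lengths), standardized effect
    sizes of phylogenetic turnover under a tip-shuffling null model,
    Mantel correlations between dissimilarity matrices, agglomerative
    clustering under eight linkage functions scored by cophenetic
    correlation and Gower's distance, silhouette-guided choice of the
    number of regions, and non-metric multidimensional scaling with
    multiple random starts. Includes a synthetic-flora generator that
    plants hierarchical realm/region structure on simulated phylogenies
    so the full pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    cluster,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    picante,
    withr,
    optparse
Config/testthat/edition: 3
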