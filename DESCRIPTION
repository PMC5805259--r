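Package: oralvirome
Title: Oral DNA Virome Profiling from Dual-Database Alignment Hits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for profiling oral DNA virome communities from
    tabular nucleotide-alignment hits against viral and bacterial reference
    databases. Implements threshold-based hit filtering, best-hit and
    lowest-common-ancestor (LCA) taxonomic read assignment, partitioning of
    viral reads by reference class (prophage, bacteriophage, eukaryotic
    virus) and by dual-database homology, taxon-by-sample count tables with
    BIOM 1.0 export, core-virome prevalence categorisation with singleton
    detection, rarefaction, and Shannon alpha / Bray-Curtis beta diversity
    group comparisons using Monte Carlo permutation t-tests with multiple
    testing correction. Ships a synthetic community and hit-table generator
    with ground truth so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vegan,
    biomformat
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
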