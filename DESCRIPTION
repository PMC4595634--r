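Package: exoniche
Title: Exometabolite Niche Partitioning from Untargeted LC-MS Footprinting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for exometabolomic (metabolic footprinting)
    experiments on microbial isolates. Resolves redundant LC-MS spectral
    features into putative metabolites by retention-time/correlation
    grouping, adduct and isotope annotation, neutral-mass inference and
    CHNOPS molecular-formula assignment from accurate mass and relative
    isotopic abundance. Classifies per-isolate metabolite uptake and
    release from spent-versus-control medium comparisons, and derives
    niche-partitioning statistics: per-isolate used fractions, shared-use
    distributions, competition and cross-feeding candidate sets, pairwise
    niche overlap and a bipartite isolate-metabolite network. Includes a
    cell-extract release-breadth analysis, a soil-water wetting time-course
    analysis, and a synthetic-data generator emulating the statistical
    structure the pipeline assumes.
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
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
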