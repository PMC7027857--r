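Package: rootpore
Title: Root-Macropore Interaction Analysis in Repacked Soil Columns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying wheat root-macropore interactions in X-ray
    CT mesocosm experiments with loose and compacted subsoil. Builds parametric
    two-layer soil columns with artificial vertical macropores, simulates 3D
    root trajectories with configurable pore-interaction behaviour, voxelizes
    scenes into labelled or grayscale CT phantoms, recovers root centerlines by
    seeded region growing and distance-guided skeletonization, classifies each
    root-pore interaction as colonization or crossing (in-pore arc-length rule)
    and as trajectory change or no change (pre/post direction fit with an
    angular threshold), and summarises experiments with randomized-block ANOVA
    and least significant differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    tiff,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
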