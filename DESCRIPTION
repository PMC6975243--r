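Package: facetmorph
Title: Sphere-Fit Morphometry of Articular Facet Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantitative morphometry of small articular surfaces
    digitised as triangle meshes, developed around the carpometacarpal facets
    of the hamate and the fourth and fifth metacarpal bases. Implements
    geometric least-squares sphere fitting (radius of curvature with mean
    absolute and percentage error), mid-sagittal/mid-coronal cross-section
    length and width, three-point radius of curvature, bicondylar
    decomposition of a joint surface into two overlapping spheres with area
    fractions and an angle of divergence, dorsal-flattening detection, and
    inter-facet angles. A synthetic-surface generator produces ground-truthed
    spherical caps, flattened caps, bicondylar patches and whole simulated
    specimen cohorts emulating laser-scanned facet patches, so every pipeline
    stage is testable without scan data. Meshes are read and written in PLY,
    STL and OBJ.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
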