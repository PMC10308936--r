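Package: duofilm
Title: Quantification of Spatial Organization in Dual-Species Phototrophic Biofilms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for quantifying the spatial organization of a
    two-species phototrophic biofilm (a filamentous cyanobacterium imaged
    through chlorophyll/phycocyanin autofluorescence in the red channel,
    and an eGFP-tagged heterotrophic rod in the green channel) from
    confocal z-stacks. Provides a synthetic phantom generator with
    voxel-level ground truth, dual-channel threshold segmentation with
    cross-channel masking, depth-stratified biovolume percentages and
    species ratios, lateral fluorescence-intensity profiles and
    co-localization scores, within-sample protein abundance ranking with
    condition-exclusive detection calls, and colony-count accounting of
    resident versus detached cells.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
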