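Package: streamdisturb
Title: Disturbance Scoring and Fish Assemblage Responses in Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores human disturbance of stream sites at the local scale
    (proximity-weighted tallies of eleven disturbance categories along
    in-stream transects), the catchment scale (weighted land-use
    percentages), and their Euclidean combination, the Integrated
    Disturbance Index (IDI), together with a 22-parameter rapid habitat
    diversity assessment. Quantifies fish assemblage responses along the
    disturbance gradient: taxonomic diversity indices, occupancy-based
    species restrictedness, indicator species analysis (IndVal) with
    permutation inference, Spearman correlation screening with
    collinearity (VIF) filtering, and distance-based redundancy analysis
    on Bray-Curtis dissimilarities with permutation tests. Includes a
    synthetic landscape and assemblage generator with planted effects so
    the complete pipeline can be exercised and validated without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
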