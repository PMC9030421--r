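Package: seedmorph
Title: Seed Silhouette Morphometry and Stepwise Discriminant Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based geometric morphometrics for seeds, fruit stones and
    endocarps scanned on uniform backgrounds. Segments flatbed-scanner images
    into per-specimen binary silhouettes, traces pixel-centre boundary
    polygons, computes a panel of 26 shape descriptors (perimeter, area,
    Feret diameter, breadth, convex-hull measures, minimal bounding circle,
    and the classical dimensionless ratios such as circularity, roundness,
    solidity, convexity and rectangularity), and classifies specimens with
    stepwise linear discriminant analysis driven by Wilks' lambda partial-F
    statistics, including leave-one-out cross-validation and allocation of an
    unknown specimen group (e.g. archaeological material) to modern reference
    classes. A synthetic superellipse silhouette generator with analytic
    ground truth supports validation without physical collections.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
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
    MASS,
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
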