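Package: charstack3d
Title: 3D Reconstruction and Volume Morphometry of Charcoal Particles from
    Confocal Reflectance Z-Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies charcoal abundance in palaeofire samples as total
    particle volume rather than particle count. Reads reflectance confocal
    z-stacks with explicit anisotropic voxel spacing, segments bright
    particles on a dark background (fixed or automatic inter-class-variance
    threshold, small-object and area filters, optional deletion of a
    bottom-slice reflection artifact), labels particles by 3D connected
    components, extracts a watertight triangle surface per particle and
    computes enclosed volume, surface area and triangle count, and derives
    per-particle morphometrics (projected area, bounding-box extents,
    manual length-width-depth volume estimate, ellipsoid-equivalent
    semi-axes, oblate/prolate shape class, circularity, aspect ratio).
    Assemblage-level tools summarise size distributions, estimate total
    sample volume from particle count and median particle volume, fit the
    area-volume conversion regression, compare samples by Kruskal-Wallis
    rank tests, and measure size sorting. A synthetic-stack generator
    renders ground-truthed assemblages of oblate ellipsoids for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
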