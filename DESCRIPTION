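Package: diaphragmCT
Title: Automated Diaphragm Configuration Analysis from Chest CT Lung Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts the lung-diaphragm intersection from chest-CT lung or
    lobe segmentations and quantifies diaphragm configuration as the
    diaphragm index, the ratio of diaphragm surface area to its axially
    projected area (1 = flat, 2 = hemispherical dome). The per-coronal-slice
    algorithm isolates the caudal lung boundary by outline cutting at the
    costophrenic recesses, filters non-diaphragm slices, and stitches the
    retained arcs into a single connected 3D surface. Includes spherical-cap
    phantom generation with analytic ground truth for validation, -950 HU
    emphysema densitometry, and cohort-level IQR outlier screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
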