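Package: spotzone
Title: Tumor-Margin Zonation Analysis for Spot-Based Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying the invasive margin of solid
    tumors in spot-based spatial transcriptomics (50-micron binned data).
    Given deconvolved per-spot cell-type abundances, the package assigns
    spots to cell types with a ratio-percentile rule, detects the tumor
    region from a malignant-cell abundance raster (threshold, Gaussian
    blur, Canny edges, contour refinement), extracts the tumor borderline,
    partitions the surrounding tissue into six 500-micron zonal bands by
    signed distance, computes per-band cell-type composition with
    rank-sum enrichment tests, flags differentially expressed genes,
    scores gene sets against expression-matched controls, and derives
    per-spot copy-number burden from a 250-gene sliding-window profile
    against a normal reference. A synthetic-section simulator with
    planted tumor geometry, stromal gradients and CNV blocks provides
    ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    EBImage,
    mgcv,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
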