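Package: recistvar
Title: Measurement Uncertainty of Manual 2D Tumour Segmentations for
    RECIST 1.1 Response Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies inter-observer variability of manual two-dimensional
    tumour segmentations and its impact on RECIST 1.1 response calls.
    Extracts the two RECIST metrics (maximum diameter via convex hull and
    rotating calipers, area via the shoelace formula) from multi-reader
    contour polygons, applies a consensus-slice rule to exclude aberrant
    segmentations, summarises per-tumour dispersion (mean, SD, coefficient
    of variation), computes inter-observer agreement as an intraclass
    correlation from repeated-measures ANOVA, regresses segmentation SD on
    lesion size per organ, builds 95% confidence bands around the stable
    disease, progressive disease (+20%) and partial response (-30%) limit
    lines, and solves for the lesion sizes above which response calls are
    indistinguishable from measurement noise.  Includes a synthetic
    multi-reader contour generator so the full pipeline is testable without
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
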