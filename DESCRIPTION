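Package: ccfd
Title: Choriocapillaris Flow-Deficit Quantification from En-Face OCTA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of choriocapillaris (CC) flow deficits from paired
    structural and flow en-face optical coherence tomography angiography (OCTA)
    images. Implements the standard Fiji-style processing chain as reusable,
    tested functions: CC slab definitions below Bruch's membrane and en-face
    projection from small volumes, shadow-artifact compensation by the inverted
    and blurred structural slab, Phansalkar local adaptive thresholding over a
    circular window, and four particle metrics (flow-deficit percentage, count,
    mean size, total area) with physical-unit scaling. A synthetic en-face OCTA
    generator with known ground truth (capillary mesh with realistic
    intercapillary spacing, planted flow voids, drusen-like shadowing, per-device
    sampling and noise) supports validation, and a statistics layer provides
    paired exact Wilcoxon signed-rank tests, ICC(2,1) agreement, repeated-measures
    ANOVA with Tukey post-hoc comparisons, and device-by-slab summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
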