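Package: nvcfuse
Title: Multimodal MRI Fusion and 3D Visualization of Neurovascular
    Compression at the Brainstem
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building three-dimensional visualizations of
    neurovascular relationships at the ventrolateral medulla from paired
    anatomical (CISS-like, hyperintense cerebrospinal fluid) and
    angiographic (TOF-like, hyperintense vessels) MRI volumes.  Provides
    a synthetic phantom generator with ground truth and the principal
    artifact classes (flow voids, CSF pulsation speckle, near-brainstem
    contour fusion), anisotropic-diffusion and grey-closing
    preprocessing, seeded volume-growing segmentation with a label
    priority hierarchy, landmark plus mutual-information rigid
    registration over a resolution pyramid, TOF-to-CISS vessel transfer
    by intensity inversion, label-aware direct volume rendering to PNG,
    vessel-nerve contact detection, an ordinal 0-5 vessel-quality score,
    and the paired t, chi-square and Levene statistics used to compare
    visualization quality before and after fusion.  Includes minimal
    self-contained NIfTI-1 and PNG I/O so the pipeline runs without
    imaging toolkits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
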