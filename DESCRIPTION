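Package: petlesionsim
Title: Synthetic Lesion Insertion and Attenuation-Correction Evaluation for PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained simulator for assessing PET attenuation-correction
    (AC) methods with sinogram-domain synthetic lesion insertion. Generates
    pelvis-like digital phantoms (tissue labels, activity, Hounsfield units),
    derives 511 keV attenuation maps from CT numbers (CTAC) and from a
    Dixon-style bone-free segmentation (MRAC), forward-projects activity
    through a parallel-beam system model with attenuation, normalization and
    Poisson noise, reconstructs with ordered-subsets expectation maximization
    (OSEM) including an image-space PSF model, and quantifies the SUV
    consequences of the AC choice: SUV Error Ratios, Lesion Error Ratios,
    Bland-Altman agreement, voxel-wise SUV difference percentages and their
    mean / standard deviation / RMSE / maximum summaries.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
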