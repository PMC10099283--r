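Package: tactoscope
Title: Optical Tactile-Sensation Imaging: Waveguide Physics, Synthetic
    Phantoms and Nodule Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computational core of a total-internal-reflection (TIR)
    tactile-sensation imaging system for stiffness-based nodule screening.
    Solves the guided TE modes of a four-layer elastic slab optical
    waveguide (dispersion residual, bisection mode search, field
    reconstruction), computes geometric-optics acceptance angles and the
    LED injection cone, ray-traces light scattering from a deformed
    waveguide surface, generates synthetic tissue-phantom tactile images
    parameterised by inclusion elasticity, depth and size, and analyses
    tactile images: fuzzy-entropy binarization, morphological nodule
    segmentation with contour tracing, calibrated elasticity surfaces
    with peak-stiffness estimation, and sensitivity/specificity/ROC
    evaluation of presence-absence detection on labelled cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
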