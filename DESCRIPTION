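Package: flowgrade
Title: Automatic Facial-Paralysis Grading from Laser Speckle Contrast Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automatic House-Brackmann grading pipeline for unilateral
    facial paralysis based on laser speckle contrast imaging (LSCI).
    Registered colour/blood-flow image pairs are segmented into fourteen
    facial regions by fitting a PCA morphable face model to 68 facial
    landmarks (gold-standard affine camera estimation followed by a
    closed-form ridge solve of the shape coefficients), regional mean
    perfusion is extracted and min-normalised into a scale-free
    affected/healthy feature vector, and House-Brackmann grade is
    predicted with K-nearest-neighbour, polynomial-kernel SVM and
    two-hidden-layer neural-network classifiers under patient-grouped
    k-fold cross-validation. Includes a synthetic LSCI cohort simulator
    (face model, posed renders, grade-dependent perfusion asymmetry,
    motion artifacts, speckle physics) providing ground truth for every
    stage, plus Dice-coefficient segmentation evaluation and a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    EBImage,
    e1071,
    jsonlite,
    tiff,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    class,
    withr,
    optparse
Config/testthat/edition: 3
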