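Package: ustiff
Title: Whole-Breast Stiffness Mapping from Transmission Ultrasound Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of whole-breast ultrasound tomography
    image stacks. Builds a relative bulk-modulus surrogate ("stiffness
    fusion") map from co-registered sound-speed and attenuation volumes,
    segments the breast into six tissue components (fat/fibroglandular by
    sound speed crossed with soft/intermediate/hard by stiffness) using
    per-breast K-means clustering, computes voxel-count volumetrics and
    cohort summaries, applies a high-pass spatial filter that suppresses
    structures larger than 1.5 cm to emphasize masses, and derives per-mass
    metrics (0-1 stiffness index, stiffness-class percentages, gray-level
    co-occurrence homogeneity, size class) with Welch t and chi-squared
    group comparisons. Includes a synthetic digital breast phantom
    generator with ground-truth labels for validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
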