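Package: isimap
Title: Intrinsic Signal Imaging Retinotopy: Phase Maps, Visual Field Sign,
    and Reliability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end processing of periodic-stimulation intrinsic signal
    imaging (ISI) experiments for retinotopic mapping of mouse visual cortex
    through an intact skull. Converts reflectance image stacks to absorbance
    via the modified Beer-Lambert law, extracts per-pixel responses at the
    stimulus drift frequency by exact-frequency Fourier projection, rejects
    low-quality trials, cancels the hemodynamic delay by combining opposing
    sweep directions, converts phase to visual degrees, computes visual field
    sign (VFS) maps and segments signed cortical areas, quantifies map
    reliability as a function of trial count (centroid error curves and
    ROC/AUROC detectability), aligns maps to vasculature and craniotomy
    images by rigid translation, and validates imaging-derived retinotopy
    against laminar local field potential recordings. A synthetic-data
    generator with known ground truth (retinotopic layouts, reflectance
    movies, vasculature images, laminar LFP responses) makes every stage
    testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
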