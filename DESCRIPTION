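Package: wrdmd
Title: Motion Correction of Dynamic Contrast-Enhanced Image Sequences by
    Windowed and Reconstruction Dynamic Mode Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Registration-free motion correction for dynamic contrast-enhanced
    (DCE) image sequences such as renal DCE-MRI. A sliding-window dynamic mode
    decomposition (W-DMD) separates each short window of frames into a low-rank
    image and a sparse residual, suppressing pseudo-periodic breathing motion;
    a full-sequence DMD of the low-rank stream followed by truncated
    reconstruction from the most significant modes (R-DMD) yields a
    motion-stabilised sequence. Includes exhaustive-search block-matching
    motion estimation, region-of-interest time-intensity curve analysis with a
    scale-invariant degree-of-smoothness score, a seeded synthetic renography
    phantom generator with ground truth, readers and writers for TIFF, PNG and
    NIfTI stacks, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    png,
    RNifti,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
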