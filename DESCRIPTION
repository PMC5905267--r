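Package: afmflatten
Title: Automated Segmentation-Assisted Flattening of Atomic Force Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step automated flattening of atomic force microscopy (AFM)
    height images. Convex and concave foreground features (nanobubbles, pits)
    are first segmented by adaptive local-mean thresholding followed by a
    greedy active-contour ("contour expansion") refinement, and the detected
    regions become exclusion masks. The image background is then estimated by
    polynomial fitting restricted to background pixels -- per scan line, as a
    full surface, or with sliding-window curve/surface variants for complex
    background trends -- and subtracted. Includes a seeded synthetic scene
    generator with ground truth, cross-section morphometry (pit depth),
    residual and mask-agreement statistics, a two-pass segment-flatten-segment
    pipeline, float-TIFF and text-matrix image I/O, and a command-line front
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
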