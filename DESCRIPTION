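Package: edofscope
Title: End-to-End Learned Flat Optics for Extended Depth-of-Field Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing computational extended depth-of-field (EDOF)
    microscopes built around a 4f system with a learned phase mask at the
    Fourier plane. Provides a differentiable wave-optics forward model
    (defocus calculus, pupil assembly, FFT-based point spread functions),
    learnable phase-mask parameterizations (diffractive element height maps,
    metalens nanopillar radius maps via phase-radius lookup tables, cubic
    masks), sensor image formation with Gaussian noise, a U-Net deblurring
    network with a residual output head, two-stage end-to-end training,
    and evaluation utilities (PSNR, SSIM, MTF bandwidth and depth-invariance,
    fabrication-error robustness). A synthetic texture generator supplies
    multi-scale grayscale training data so the whole pipeline runs without
    external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
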