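Package: usginpaint
Title: Mask-Guided Adversarial Inpainting for Annotated Ultrasound Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removes clinician-drawn annotation symbols (caliper crosses, dashed
    lesion outlines, letters and digits) from 2D ultrasound images by free-form
    image inpainting with a mask-guided generative adversarial network. The
    generator combines fast Fourier convolution residual blocks (a local spatial
    path plus a global spectral path) with squeeze-and-excitation channel
    attention; training masks are composed so that they never overlap the
    symbol regions, whose true background is unknown. Includes a seeded
    synthetic ultrasound-phantom generator with exact symbol masks, irregular
    brush-stroke mask generation, the four-term training loss (L1, adversarial,
    high-receptive-field perceptual, discriminator-feature), SSIM / Frechet
    distance / LPIPS-style / mIoU evaluation metrics, and a small
    reverse-mode neural-network engine in base R on which everything runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
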