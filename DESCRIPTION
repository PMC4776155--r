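Package: micsr
Title: Multimodal Image Correlation Spectroscopy for Live-Cell Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fluctuation-based analysis of time-lapse confocal image stacks.
    Implements multimodal image correlation spectroscopy (mICS): spatiotemporal
    correlation of intensity fluctuations over pixel shifts and frame lags,
    fitted per lag with a two-component (isotropic + anisotropic) Gaussian
    mixture selected by a likelihood-ratio test, and mapped in sliding windows
    across a cell. Also provides raster image correlation spectroscopy (RICS)
    diffusion fitting, photobleaching correction, pixel-shift Pearson
    co-localization, kymograph extraction, a raster-scanned synthetic image
    simulator of point emitters under diffusion, binding, confined/oscillating
    and directed motion, and a one-dimensional Monte Carlo simulator of
    nucleocytoplasmic translocation with a permeable nuclear envelope.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    yaml,
    jsonlite,
    minpack.lm,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
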