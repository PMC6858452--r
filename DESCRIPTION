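Package: podopipe
Title: Podosome Nano-Architecture Morphometry, Flow Mapping and Mesoscale
    Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative image analysis of podosome clusters in fluorescence
    microscopy: synthetic scene generation with known ground truth (cores,
    adaptor rings, dorsal/ventral planes, oscillating time series, gelatin
    degradation fields), rotating-line radial intensity profiling with
    Gaussian fits of core FWHM and ring diameter, orthogonal-view z-height
    analysis, cluster morphometrics (area, nearest-neighbor distance,
    degradation index), sliding-time-window spatiotemporal image correlation
    spectroscopy (twSTICS) velocity mapping, and pair vector correlation
    (PVC) analysis of flow coordination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
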