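Package: fluortof
Title: Fluorescence Time-of-Flight Depth Sensing in Turbid Media
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for depth sensing of fluorescent inclusions in turbid
    media from time-gated single-photon imaging. Simulates gated SPAD
    time-scan acquisitions (instrument response, reflectance and
    fluorescence modalities with binomial pile-up photon statistics),
    fits temporal profiles with a convolution model (instrument response
    convolved with a Gaussian medium transfer function and, for
    fluorescence, a mono-exponential decay), builds linear calibration
    chains relating time of flight to inclusion depth via medium
    scattering, inverts time-of-flight maps to depth maps, and corrects
    surface intensity for depth attenuation using the effective
    attenuation coefficient.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    minpack.lm,
    tiff,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
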