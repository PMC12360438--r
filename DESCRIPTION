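Package: sonomech
Title: Mechanistic Simulation of Mechanotherapy, Sonopermeation and
    Nano-Immunotherapy in Solid Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, spherically symmetric simulator of solid-tumor
    response to combined mechanotherapy (ketotifen), ultrasound microbubble
    sonopermeation, and nano-immunotherapy (liposomal doxorubicin with
    anti-PD-1 and anti-CTLA-4 checkpoint antibodies). Implements three-state
    nanocarrier transport with Starling transvascular exchange and hindered
    pore transport, acoustic-pressure-dependent vessel-wall pore dilation and
    microstreaming wall shear stress, stiffness-dependent vessel compression,
    interstitial fluid pressure, tumor-microenvironment population dynamics
    (cancer, immune and endothelial cells, angiogenic factors, oxygen), a
    treatment scheduler for the eight experimental arms, and an
    order-and-interval parametric sweep, together with calibration and
    reporting utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
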