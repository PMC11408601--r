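Package: mimsr
Title: Quantitative Analysis of Multiplexed Stable-Isotope Imaging of Nuclear RNA and DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative multi-isotope imaging mass spectrometry
    (MIMS/NanoSIMS) of newly synthesized RNA and DNA within single nuclei.
    Computes per-pixel and per-ROI isotope ratios and percent-above-background
    enrichment with Poisson counting errors, renders hue-scaled enrichment
    images, segments nuclear compartments from structural ion channels,
    detects top-ranked square hotspot windows with complementary-label
    colocalization, and summarises pixel populations (regressions, robust
    dispersion, top-percentile density subsets, pulse-chase tables). Includes
    a seeded synthetic scene simulator with Poisson ion-counting noise and
    full ground truth, so every analysis is testable without an instrument,
    plus a configuration-driven pipeline that writes TIFF/PNG/TSV/JSON
    artifacts with a run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
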