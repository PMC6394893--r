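Package: photoscreen
Title: Phototoxicity Screening of Natural Extracts from Microplate Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a low-cost photosensitizer screening
    workflow. Quantifies relative singlet-oxygen production from
    9,10-dimethylanthracene (DMA) absorbance-quenching time courses on
    96-well plates, corrected by the sensitizer's probability of absorption
    at the irradiation wavelength and validated by ascorbate-quench and
    side-reaction controls. Fits four-parameter-logistic dose-response
    curves to sulforhodamine-B (SRB) photo-cytotoxicity data, computes EC50
    bootstrap confidence intervals and the dark/irradiated selectivity
    index, and classifies extracts into a five-case phototoxicity
    interpretation rubric. Includes LED-array dosimetry with ferrioxalate
    actinometry and a synthetic plate-data generator with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
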