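Package: brachyqa
Title: TG-43 Dose Engine and Commissioning QA for HDR Brachytherapy Planning Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for commissioning the TG-43 dose calculation of a
    high-dose-rate brachytherapy treatment planning system. Implements the
    line-source approximation dose-rate engine (geometry function, radial dose
    function, 2D anisotropy function), bidirectional anisotropy-table
    resampling and discrepancy detection against 2%/5% investigation and
    intervention action levels, extraction of the anisotropy function from
    along-away dose-rate tables, superposed dose planes for standard clinical
    dwell configurations (single dwell, vaginal applicators, Fletcher tandem
    and ovoids, multi-applicator implants), 2D gamma-index analysis with local
    dose normalization, and quality-assurance point patterns including a
    half-star ray layout that probes the steep dose gradients near the source
    poles. A synthetic-data module generates reference/vendor table pairs with
    realistic pole gradients so the full pipeline is testable without
    proprietary vendor data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
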