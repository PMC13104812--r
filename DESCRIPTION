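Package: fluxslice
Title: Stable-Isotope Fluxomics of Tumor Tissue Slice Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for stable-isotope tracing experiments in tissue
    slice cultures: mass isotopologue distribution (MID) algebra, natural
    isotope abundance correction from elemental formulas (including
    derivatization atoms), isotopomer spectral analysis (ISA) of fatty acid
    synthesis with profile-likelihood confidence intervals, moiety-convolution
    lipid metabolic flux analysis of elongation and glycosphingolipid
    networks, deuterated-water (D2O) fraction-new calculations, biomass
    fractional-synthesis ratios, and a synthetic-data generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    minpack.lm,
    utils,
    pracma,
    jsonlite,
    yaml,
    withr,
    lhs
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
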