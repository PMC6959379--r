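Package: meshbagr
Title: Chemical and Community Change in Mesh-Bag Organic Matter After Fungal Colonization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mesh-bag litter-decomposition experiments in
    forest soil: deconvolution of C and N K-edge NEXAFS spectra into Gaussian
    pi* components over an error-function edge jump, with relative pi*
    abundances per chemical class; stable-isotope (delta 13C) two-pool mixing
    to quantify new fungal carbon in C4-plant compost; one-compartment decay
    constants and partitioning of the C/N-ratio increase into fungal-biomass
    and inorganic-N-leaching contributions; FTIR fingerprinting with band
    integrals and PCA; and ITS OTU-table processing (rare-OTU filtering,
    technical-replicate averaging, rarefaction, guild profiles, Bray-Curtis
    dissimilarity, PERMANOVA). A synthetic-data generator with known ground
    truth drives all stages so every step is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    pracma,
    rlang,
    stats,
    utils,
    vegan,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
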