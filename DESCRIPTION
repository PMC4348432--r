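Package: nmrbits
Title: Metabolite Identification Information Content for NMR Metabolomics
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the metabolite identification information that 1D and
    2D 1H NMR spectroscopy can provide for small-molecule metabolites.  From a
    molecular structure the package derives proton equivalence classes
    (including diastereotopic methylene splitting), counts the theoretically
    observable identification information bits (chemical shifts,
    multiplicities, scalar couplings, second-order flags and COSY/HSQC/HMBC
    cross-peaks), tallies the bits actually observed in experiments, and
    computes the metabolite identification efficiency indices MIE (bits per
    heavy atom), MICE (bits per carbon) and MIHF (observed over theoretical
    bits).  Observed shifts and couplings can be matched against reference
    data under ppm/Hz tolerances, molecular coverage is assessed, and each
    identification is classified as confidently identified or putatively
    annotated.  A curated 75-metabolite urinary cohort, cohort-level
    statistics and a seeded synthetic observation generator are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    ChemmineR,
    ChemmineOB
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
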