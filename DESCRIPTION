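Package: ldrua
Title: Ligase Detection Reaction Universal Array Design, Simulation and
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for phylogenetic fingerprinting of microbial
    communities with Ligase Detection Reaction (LDR) probes read out on a
    ZipCode Universal Array. Extracts IUPAC consensus sequences from
    aligned 16S rRNA target groups, designs Discriminating/Common probe
    pairs under nearest-neighbor melting-temperature and 3'-mismatch
    specificity constraints, models multi-subarray ZipCode layouts with
    replicate and control spots, simulates LDR experiments on template
    mixtures with multiplicative spot noise, calls probe presence against
    a blank-spot null distribution with a one-sided t-test, and turns
    call tables into presence/absence fingerprints, relative fluorescence
    contributions and Ward-linkage sample clusterings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
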