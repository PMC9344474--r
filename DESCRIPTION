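Package: dnahydro
Title: Knowledge-Based Prediction of DNA Hydration from Dinucleotide Building Blocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives hydrated dinucleotide building blocks (conformer- and
    sequence-specific water probability densities and hydration sites) from
    collections of DNA crystal structures, and uses them to predict and
    evaluate the first hydration shell of arbitrary DNA molecules. Provides
    curation of sequentially nonredundant chain sets, dinucleotide step
    extraction with conformer-class bookkeeping, water association and
    rigid-body transfer onto reference dinucleotides, Gaussian water
    probability density grids with peak detection, whole-structure hydration
    prediction by block overlay, and a fully synthetic corpus generator for
    self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
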