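Package: numtfossil
Title: Dating Nuclear Mitochondrial Pseudogenes and Testing Hybridization Scenarios
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for treating nuclear pseudogenes of mitochondrial DNA (NUMTs)
    as "mtDNA fossils". The package estimates how diverged a NUMT's mitochondrial
    precursor was at the time of its insertion into the nuclear genome, using a
    delete-half jackknife over alignment columns with model-corrected distances and
    least-squares branch-length re-fitting on a fixed topology. Stem and
    post-insertion mutations are mapped to branches by Fitch parsimony and
    classified as synonymous or non-synonymous under the vertebrate mitochondrial
    code, giving a contrast test that identifies stem mutations as mitochondrial.
    A linear molecular-clock calibration converts divergence to time, a regression
    of intra-taxon mtDNA divergence on nuclear effective population size tests the
    large-ancestral-population alternative, and a shared-stem statistic
    discriminates NUMT-transfer from mtDNA-introgression histories. A two-phase
    (purifying selection, then neutral pseudogene) sequence-evolution simulator
    with full ground-truth bookkeeping exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phytools,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
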