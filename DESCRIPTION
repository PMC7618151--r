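Package: recombmapr
Title: Recombination Map Inference from Bulk Gamete Hi-C Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers individual recombination landscapes from bulk-gamete
    chromosome conformation capture (Hi-C) sequencing. Detects
    crossover-informative read pairs against phased donor haplotypes,
    estimates and corrects the false-positive crossover rate from the
    insert-size distribution, reconstructs a per-basepair recombination
    map by an expectation-maximisation procedure, and quantifies
    uncertainty by bootstrap resampling of read pairs. Includes a
    simulator of informative read pairs from a reference map for method
    evaluation, a Mendelian trio-phasing utility, and readers/writers
    for HapCUT2 phased-block and tabular map formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    optparse,
    Rsamtools,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
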