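Package: karyoevol
Title: Comparative Cytogenetic Maps and Karyotype Rearrangement Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative cytogenetic analysis of multi-species
    gene-location tables. Parses cytogenetic location strings (chromosome,
    arm, band intervals, microchromosome and sex-chromosome annotations),
    derives pairwise conserved synteny segments, classifies chromosomes by
    macro- versus microchromosome origin against avian macrochromosome
    units, and infers phylogenetically polarized karyotype rearrangement
    events (centric fusion and fission, tandem fusion, inversion) by
    outgroup parsimony on a fixed species tree. Ships a comparative map
    of 86 functional genes across the Hokou gecko, five other squamate
    reptiles and the chicken, together with karyotype, rDNA and
    interstitial-telomeric-site landmark tables, and a karyotype-evolution
    simulator with known ground truth for validating event recovery.
License: MIT + file LICENSE
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Encoding: UTF-8
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
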