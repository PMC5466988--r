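Package: ecogmap
Title: Intraoperative ECoG Motor Cortex Mapping from Movement-Related
    Cortical Potentials and Spectral Power Changes
Version: 0.1.0
Authors@R:
    person("ecogmap", "developers", email = "ecogmap@example.org",
           role = c("aut", "cre"))
Description: Functional motor cortex mapping from intraoperative
    electrocorticography (ECoG). Implements temporal alteration mapping:
    per-trial correlation of the movement-related cortical potential
    (MRCP, 0.05-3 Hz) against a 500 ms template, summarised per channel
    by a signed R-squared statistic with ANOVA significance testing.
    Includes the spectral comparator (frequency alteration mapping from
    8-32 Hz and 66-90 Hz band power changes), evaluation of either map
    against electrical-stimulation ground truth (confusion counts,
    sensitivity/specificity, Yates chi-square), Gaussian-kernel
    topographic activation maps, and a seeded synthetic ECoG + EMG
    generator with ground-truth effect channels so the whole pipeline is
    testable without patient data. Reads and writes European Data Format
    (EDF) signal files, CSV event/geometry tables and JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
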