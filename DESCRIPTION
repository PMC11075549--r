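Package: vernaliza
Title: Vernalization-Response Traits and Polygenic Selection Scans in Structured Selfing Plant Panels
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline linking vernalization-response phenotypes,
    environment, and polygenic selection signals in structured, highly selfing
    plant diversity panels. Provides genotype I/O and filtering for GT-only VCF,
    extraction of four flowering-time-related traits (minimum threshold duration
    of vernalization, days to flower after it, vernalization saturation, and
    days to flower after saturation) from replicated cold-treatment experiments
    with censoring, redundancy analysis with permutation-based double-stopping
    forward selection, per-SNP Weir-Cockerham F_ST with a forward-simulation
    neutral null, a covariance-aware X^T^X differentiation statistic calibrated
    on pseudo-observed datasets, intra- and inter-chromosomal linkage
    disequilibrium with resampling nulls for focal gene sets, and a linear
    mixed-model genome-wide association scan with centered kinship, FDR control,
    and windowed peak calling. A forward Wright-Fisher simulator of selfing,
    split/bottleneck demographies generates the synthetic study designs used to
    exercise and calibrate every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
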