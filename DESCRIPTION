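Package: domadmix
Title: Supervised Estimation of Domesticated-Salmon Admixture and Its
    Phenotypic Correlates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying introgression of domesticated Atlantic
    salmon into wild populations and relating individual admixture to life
    history traits. Implements genotype quality control by call rate,
    per-locus Weir-Cockerham F_ST, DAPC locus contributions, joint top-quantile
    marker-panel selection, supervised two-population admixture estimation
    (Gibbs sampler and deterministic EM engines) with reference-based affine
    calibration, accuracy validation on simulated F1 hybrids, and linear and
    binomial-logit admixture-phenotype association models with predictions at
    fixed admixture levels. A synthetic-data module generates Balding-Nichols
    diverged populations, admixed individuals, hybrids, missingness patterns
    and phenotypes so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
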