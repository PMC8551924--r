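Package: cnassoc
Title: Copy-Number-Dependent Drug Susceptibility Screening for Mutationally Quiet Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrates gene-level tumor copy-number profiles with
    patient-derived-culture drug-screen cytotoxicity. Provides a synthetic
    cohort generator emulating arm-level segmental chromosomal aberrations,
    focal amplification, plate-based viability screening with vehicle and
    positive controls, and sparse somatic variants; probe-to-gene copy-number
    segmentation and somatic variant filtering; DMSO-normalized cytotoxicity
    with plate QC and hit calling; an all-pairs gene-by-drug Pearson
    correlation screen with Fisher z-transformation and Benjamini-Hochberg
    false-discovery-rate control, expected-target classification and
    effect-size ranking; and a Gaussian pairwise Markov-random-field model
    over a functional-interaction network with a permutation null for
    impact-score gene selection, drug overlay, z-score-weighted networks,
    and subnetwork clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
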