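Package: propellerscan
Title: WD40 Repeat Detection and Beta-Propeller Secondary Structure
    Prediction from Protein Sequence
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects WD40 repeats in protein sequences, assembles them into
    beta-propeller domains and emits per-residue secondary structure. Repeats
    are scored with a structure-anchored position-specific log-odds profile
    combined with loop-length preference scores, a bonus for the conserved
    DHSW hydrogen-bonded tetrad, and an optional term from an external
    secondary-structure prediction. Candidate repeats are combined into
    domains by a genetic algorithm with an exact dynamic-programming oracle,
    and proteins are classified as WD40 or not from the average repeat score
    and tetrad evidence. Includes profile training from annotated repeat
    alignments, a synthetic-sequence generator with ground truth, and
    evaluation metrics (Q3, loose/tight repeat recovery, jack-knife).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'template.R'
    'AllClasses.R'
    'AllGenerics.R'
    'profile.R'
    'default-profile.R'
    'profile-io.R'
    'scoring.R'
    'detection.R'
    'io.R'
    'synthetic.R'
    'propellerscan-package.R'
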