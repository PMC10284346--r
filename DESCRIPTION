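Package: pseOMP
Title: Outer Membrane Protein Prediction from Pseudo Amino Acid Composition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts bacterial outer membrane proteins (OMPs) from primary
    sequence. Protein sequences are encoded as type-I pseudo amino acid
    composition (Pse-AAC) vectors: the 20 residue fractions augmented with
    lambda weighted sequence-order correlation factors computed from
    standardized physicochemical indices (hydropathy, polarity, solvation
    free energy by default). A radial-basis-function support vector machine
    separates OMPs from non-OMPs; jackknife (leave-one-out) cross-validation,
    sensitivity/specificity/MCC/overall- and average-accuracy/auROC metrics,
    and a grid search over the encoding weight, lambda, kernel width and cost
    reproduce the published evaluation protocol. A seeded two-class sequence
    simulator with controllable compositional and sequence-order divergence
    supports calibration of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    parallel,
    Biostrings,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
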