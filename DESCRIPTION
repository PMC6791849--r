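Package: pefreseal
Title: Resealing Kinetics of Yeast Cell Envelopes After Pulsed Electric Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the recovery of the yeast cell wall and plasma membrane
    after pulsed-electric-field (PEF) permeabilization. Implements the
    pseudo-second-order tetraphenylphosphonium (TPP+) uptake law with an
    exponentially decaying, field-dependent pore term in the absorption
    coefficient, its closed-form solution with a post-pulse delay, and the
    exponential-plus-residual fluorescence decay of membrane (lipidic) pores.
    Provides algebraic calibration from printed anchor ratios, nonlinear
    least-squares fitting of pore lifetimes with shared-lifetime multi-field
    fits, synthetic-data generators mirroring the three experimental designs
    (uptake-recovery ratios, fluorescence decay series, electrode traces),
    Monte-Carlo parameter-recovery experiments, and a small file-based
    pipeline with a command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
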