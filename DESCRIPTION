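Package: gastricmill
Title: Burst, Cycle, and Rhythm-State Analysis of Stomatogastric Motor Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying gastric mill and pyloric motor rhythms from
    spike-time recordings of identified stomatogastric ganglion neurons.
    Implements interspike-interval burst detection with neuron-class-specific
    ceilings, pyloric and gastric cycle construction (including prepeak burst
    handling and pyloric interruption detection), fixed-length per-segment
    feature extraction with PCA and k-means classification of rhythm states,
    100-bin phase-profile analysis with a consecutive-bin significance
    heuristic, and the condition-comparison statistics used for such data
    (odds ratios, basic-method bootstrap confidence intervals, unbiased
    Cohen's d, rank-biserial correlation, Kendall's W, Cramer's V,
    repeated-measures correlation, and equal-slopes ANCOVA). A synthetic
    spike-train generator with ground-truth labels supports validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
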