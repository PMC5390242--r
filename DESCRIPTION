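Package: InvarianceDynamics
Title: Balanced Comparison of Object Invariances in Neural Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for a balanced comparison of object invariances (size,
    position, in-plane rotation, in-depth view) in visual neural
    populations. Generates parametric object silhouettes whose
    transformation magnitudes are solved to equate the net pixel change
    across transformations, simulates spiking populations with
    configurable invariance strength and latency per transformation,
    quantifies per-neuron invariance as tuning correlations (static and
    time-binned), performs cross-condition generalization decoding with
    a shrinkage linear discriminant including neuron-bootstrap
    peak-latency statistics, analyses invariance covariation and
    co-occurrence, and compares representations (pixel, Gabor-V1, and
    file-based deep-network features) against neural data through
    representational dissimilarity matrices with split-half reliability
    and Spearman-Brown correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
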