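Package: ndcrfs
Title: Information-Theoretic Feature Selection with Nonlinear Dynamic
    Conditional Relevance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Greedy forward feature selection for high-dimensional,
    small-sample discrete (or discretized) classification tables, scored by
    plug-in information-theoretic criteria: mutual-information maximisation
    (MIM), conditional infomax (CIFE), joint mutual information (JMI),
    conditional mutual information maximisation (CMIM), dynamic weighting
    (DWFS), dynamic relevance with joint mutual information (DRJMIM),
    dynamic weights using redundancy (DWUR), and the nonlinear dynamic
    conditional relevance criterion (NDCRFS), which normalises the
    conditional interaction penalty by a symmetric-uncertainty-style
    information gain factor. Includes class-attribute interdependence
    maximisation (CAIM) discretization, stratified cross-validated
    benchmarking with pluggable classifiers, Jaccard comparison of selected
    subsets, and a synthetic generator that plants relevant, redundant,
    interacting (parity), and irrelevant features.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    class,
    e1071,
    foreign,
    jsonlite,
    rpart,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
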