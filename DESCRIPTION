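Package: seqexpect
Title: Sequence-Learning Analysis of Deconvolved Two-Photon Population Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for visual sequence-learning experiments in
    which head-fixed mice passively view ordered grating sequences (ABCD and
    the deviants ABBD, ACBD) while layer 2/3 population activity is recorded
    by two-photon calcium imaging and deconvolved. The package builds the
    exact stimulus timetable, simulates deconvolved population activity with
    planted ground truth (element-selective, gray-onset and ramping cells,
    omission-response multipliers, multiplicative representational drift),
    aligns activity into trial tensors, classifies stimulus and context
    selectivity, computes omission and substitution prediction-error ratios
    with a hierarchical (mouse-then-cell) bootstrap, quantifies population
    geometry (PCA untangling, within-sequence decorrelation, drift curves),
    runs linear population decoders for stimulus identity, block and time,
    and estimates per-cell time fields by even/odd consistency screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
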