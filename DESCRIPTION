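Package: scramblex
Title: Sentence Scrambling, Local Mutual Information Profiling, and
    Condition-Effect Estimation for Word-Order Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing and characterizing scrambled-sentence
    stimuli of the kind used in studies of composition in the brain's
    language network. Implements skip-gram co-occurrence counting with
    Laplace smoothing, pointwise mutual information (PMI) profiles over a
    sliding four-word window, parametric local-word-swap scrambling with
    exact inversion-distance enforcement, a PMI-minimizing maximal-separation
    scrambling of content words, word-order degradation metrics (words moved
    via longest common subsequence; Kendall-tau inversion distance), a
    synthetic template language with phrase-local statistical dependencies,
    simulators for behavioral and region-of-interest neural responses with
    crossed participant and item effects, and a two-stage cluster-bootstrap
    estimator of condition contrasts under dummy or backwards-difference
    coding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
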