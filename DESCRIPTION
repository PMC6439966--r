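Package: idrhmm
Title: Reproducibility-Aware Classification of RNA Structure Probing Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies each nucleotide of a transcript into loop, stem/background,
    or unmapped states from replicated high-throughput RNA structure-probing read
    counts (case/control designs such as icSHAPE and PARS). Replicate agreement is
    modelled with a two-component Gaussian mixture copula (the irreproducible
    discovery rate, IDR) whose reproducible/irreproducible density ratios serve as
    emissions of a three-state hidden Markov model fitted by expectation
    maximization, optionally supervised by a reference secondary structure. Also
    provides the classic positional IDR baseline, raw-count and coverage-ratio
    reactivity scores, ROC/AUROC evaluation, a generative simulator for
    correlated replicate counts, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
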