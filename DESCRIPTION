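Package: distwm
Title: Connectome-Based Mean-Field Modelling of Distributed Working Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and analysis toolkit for multiregional mean-field models
    of distributed working memory in the mouse brain. Builds model-ready
    connectivity from anatomical tables (volume/density normalization,
    hierarchy completion, power-law rescaling, counterstream inhibitory bias),
    integrates stochastic rate dynamics of coupled excitatory-inhibitory local
    circuits with an optional thalamocortical extension, analyses baseline
    stability via fixed points and Jacobian eigenvalues, quantifies
    cell type-specific graph measures (input strength, eigenvector centrality,
    loop strength), performs simulated-optogenetics perturbation protocols with
    functional area classification, and enumerates multistable attractor
    states. Includes seedable synthetic-data generators so the full pipeline
    runs without external anatomical datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
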