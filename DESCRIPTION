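Package: modspan
Title: Spectral Network Analysis of Resting-State EEG with dwPLI and
    Modular Span
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for resting-state high-density EEG:
    band-limited power contributions via Welch spectra, debiased weighted
    phase lag index (dwPLI) connectivity, proportionally thresholded
    weighted graphs swept across connection densities, graph-theoretic
    metrics (weighted clustering, characteristic path length, global
    efficiency, Louvain modularity, participation coefficient), the
    topographic modular-span metric, normalised mutual information
    between modular structures, and group/clinical statistics (Welch
    t-tests with Bonferroni-Holm correction, robust regression against
    behavioural scores). Includes a synthetic-cohort generator with
    planted oscillatory network structure so that the whole pipeline is
    testable without patient recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    MASS,
    signal,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
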