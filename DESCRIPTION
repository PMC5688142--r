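Package: optoloop
Title: In Silico Closed-Loop Optogenetic Control of Single Bacterial Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A simulation sandbox for computer-interfaced optogenetic control
    of gene expression in many individual bacteria. Provides a stochastic
    virtual-cell model of a green/red light-switchable (CcaSR-type) promoter
    with latent time-varying responsiveness, growth, division and antibiotic
    perturbations; moment-equation propagation of prediction uncertainty and
    Kalman estimation of per-cell responsiveness; open-loop,
    population-level and individual-level receding-horizon controllers over
    binary light sequences; hybrid bio-digital circuits (virtual inhibitory
    signal, threshold promoter state, transfer-matrix cell-cell coupling);
    and the quantification and quality-control rules of mother-machine
    experiments (percentile-based expression extraction, growth estimation
    from log2 cell length, cell invalidation and runaway blocking), together
    with an experiment orchestrator and spectral/phase analysis utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
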