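Package: dyadflow
Title: Valence-Dependent Spectral Dynamics and Dyadic Connectivity for Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing trial-structured intracranial local field
    potential recordings from an affective-picture paradigm: signal
    conditioning (zero-phase FIR band-pass, line-noise notches, downsampling,
    bipolar re-referencing, epoching, automated spike-trial rejection),
    event-related spectral perturbation (ERSP) maps with neutral-condition
    subtraction, nonparametric cluster-based permutation statistics with
    cluster-size gating and FDR-corrected post-hoc tests, per-patient
    band-power/valence-rating association, time-varying magnitude coherence,
    Geweke spectral Granger causality with AIC order selection and
    block-permutation confidence bounds, and a reduced dynamic causal model
    for cross-spectral densities built on a linearised two-region Jansen-Rit
    neural mass model with variational-Laplace inversion and random-effects
    Bayesian model selection. A synthetic-data module generates dyadic LFP
    datasets with known spectral condition effects, known directed coupling
    and known rating-power association for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    igraph,
    EBImage,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
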