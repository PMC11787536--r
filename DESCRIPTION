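Package: tcashuffle
Title: Tensor Component Analysis with Trial-Shuffle Nulls for
    Trial-Structured Neural Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting task-independent (shared,
    condition-unrelated) signals in trial-structured neural population
    recordings such as two-photon calcium imaging during visual
    behavior.  Provides a synthetic-session generator emulating a
    periodic image/omission stimulus schedule with cell-class-specific
    response kernels and a shared trial-varying latent; event-aligned
    tensor construction and population-response quantification;
    frame-wise Spearman noise correlations with signal removal and
    trial-shuffle controls; a from-scratch canonical polyadic (CP)
    tensor decomposition fitted by alternating least squares with
    ensemble refitting; and component specificity classification with
    a within-condition trial-shuffle null that isolates shared
    task-independent structure from condition-locked responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    clue,
    rhdf5,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
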