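Package: probeload
Title: Mental Workload Classification from ERPs of Ignored Auditory Probes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing chain for estimating mental workload from
    event-related potentials (ERPs) elicited by infrequent, task-independent and
    ignored auditory probes. Provides a ground-truthed synthetic EEG/EOG generator,
    preprocessing (1-40 Hz band-pass, common average reference, epoching,
    SOBI-based ocular source cancellation, baseline correction, block decimation),
    canonical-correlation-analysis (CCA) spatial filtering learned from class-average
    ERP templates, shrinkage-regularized Fisher linear discriminant classification,
    leakage-free stratified cross-validation, ERP peak statistics, and the binomial
    chance-level threshold for decoding accuracies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    tibble,
    dplyr,
    purrr,
    rlang,
    jsonlite,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
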