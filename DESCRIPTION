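Package: ckalign
Title: Centered Kernel Alignment Feature Relevance for Neural Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Supervised feature relevance analysis for neurophysiological
    pattern detection. Learns a linear projection that maximizes the centered
    kernel alignment (CKA) between a Mahalanobis-Gaussian kernel on the
    projected features and a label kernel, and derives a per-feature relevance
    index from the learned projection. Supports relevance-based feature
    selection and a second-stage discriminative embedding, an EEG trial
    feature bank (Welch band power, Hjorth parameters, Morlet scalogram
    energies, Symlet wavelet energies, per-rhythm cepstral coefficients),
    k-nearest-neighbour evaluation under nested stratified cross-validation,
    and synthetic tabular and EEG generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
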