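Package: specfp
Title: Spectral Fingerprinting of Brain Areas from Segmented MEG/EEG Power Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterises brain areas by the repertoire of power spectra they
    express over time. Continuous source-level MEG/EEG signals are cut into 1-s
    segments, multitaper power spectra are estimated on a banded logarithmic
    frequency grid (42 frequencies, 1-120 Hz), ratio-normalised against the
    participant's grand-mean spectrum, and averaged into atlas parcels.
    Per-subject segment spectra are reduced with cosine-distance k-means and
    refined into diagonal Gaussian mixture models; subject-level components are
    clustered again at the group level with a silhouette-selected number of
    spectral modes and a majority-stability filter. Fitted area fingerprints
    support split-half classification of area identity by ranked negative
    log-likelihood, hierarchical similarity clustering of areas, and
    rest-versus-task contrasts of matched spectral modes with Welch t tests and
    sequential Bonferroni (Holm) correction. A seeded synthetic-data generator
    with known spectral modes, mode-switching proportions and subject
    variability provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
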