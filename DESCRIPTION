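Package: lfptarget
Title: Target Signatures from Deep Brain Stimulation Local Field Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding which contacts of a deep brain stimulation
    (DBS) lead carry an electrophysiological signature of the anterior
    nucleus of the thalamus (ANT). Models the bipolar-montage geometry of a
    four-contact lead, extracts a 17-feature description (statistical,
    spectral, morphological and connectivity node-strength features) of
    5-second local field potential (LFP) segments, ranks features by a
    pooled-variance t-test criterion, reduces dimensionality by principal
    component analysis at a 99 percent explained-variance threshold, selects
    a classifier among support vector machines, k-nearest neighbours and
    single-hidden-layer neural networks by nested splitting, and reports a
    per-location "target percentage" (the fraction of segments classified as
    in-target). A seeded synthetic LFP generator with location-dependent
    gamma/alpha power and cross-channel phase coupling stands in for
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    signal,
    e1071,
    nnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    class,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
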